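# Feature registry, discretization, intensity statistics and texture
# features on small hand-checkable inputs plus randomized oracle checks
# (the exhaustive small-grid equivalence sweep lives in test-acceptance.R).

roi_from_values <- function(values, nrow = 1) {
  img <- matrix(values, nrow = nrow)
  zscore_roi(img, matrix(1L, nrow(img), ncol(img)))
}

labeled_from_grid <- function(grid) {
  structure(list(labels = grid, n_levels = max(grid),
                 n_pixels = sum(grid > 0)), class = "labeled_roi")
}

test_that("the registry holds exactly 74 features incl. the named ones", {
  reg <- feature_registry()
  expect_length(reg, 74)
  expect_false(anyDuplicated(reg) > 0)
  expect_true(all(c("F.stat.kurt", "F_cm.info.corr.2", "F_rlm.glnu.norm",
                    "F_szm.glu.norm") %in% reg))
})

test_that("discretization follows the right-closed equal-width convention", {
  roi <- roi_from_values(c(-1, 0, 1) * 2)  # z-scores are (-1, 0, 1)
  lab <- discretize(roi, n_bins = 2)
  expect_identical(as.integer(lab$labels), c(1L, 1L, 2L))
  expect_error(discretize(roi, n_bins = 1), "n_bins")

  # 32 equally spaced values into 32 bins: every label exactly once
  roi32 <- roi_from_values(seq(0, 31), nrow = 4)
  lab32 <- discretize(roi32, n_bins = 32)
  expect_identical(sort(as.integer(lab32$labels)), 1:32)
})

test_that("intensity statistics match direct moment computation", {
  roi <- roi_from_values(c(1, 1, 1, 5))
  st <- intensity_statistics(roi)
  expect_equal(unname(st["F.stat.kurt"]), 21 / 9 - 3, tolerance = 1e-12)
  # direct moments of the z-scored values
  v <- roi$values
  expect_equal(unname(st["F.stat.mean"]), mean(v), tolerance = 1e-12)
  expect_equal(unname(st["F.stat.var"]), mean((v - mean(v))^2), tolerance = 1e-12)
  expect_equal(unname(st["F.stat.energy"]), sum(v^2), tolerance = 1e-12)
  expect_equal(unname(st["F.stat.rms"]), sqrt(mean(v^2)), tolerance = 1e-12)

  expect_equal(unname(intensity_statistics(roi_from_values(c(-1, 0, 1)))["F.stat.skew"]),
               0, tolerance = 1e-12)

  set.seed(5)
  big <- roi_from_values(rnorm(1e5), nrow = 250)
  expect_lt(abs(intensity_statistics(big)["F.stat.kurt"]), 0.1)
})

test_that("texture matrices agree with hand counts on tiny grids", {
  # constant 3x3 grid: single nonzero GLCM cell on the diagonal
  g <- matrix(1L, 3, 3)
  mats <- build_texture_matrices(labeled_from_grid(g))
  expect_equal(mats$glcm[1, 1], sum(mats$glcm))
  expect_gt(mats$glcm[1, 1], 0)

  # 1x4 labels (1,1,2,2): horizontal runs are one 2-run per level
  g2 <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  rlm <- build_texture_matrices(labeled_from_grid(g2))$glrlm
  # vertical/diagonal directions contribute length-1 runs (2 of each level each)
  expect_equal(rlm[1, 2], 1)
  expect_equal(rlm[2, 2], 1)
  expect_equal(rlm, oracle_glrlm(g2, 2))

  # 4-level tiling with no equal 8-neighbors: every zone has size 1
  g3 <- matrix(c(1L, 3L, 1L, 3L,
                 2L, 4L, 2L, 4L,
                 1L, 3L, 1L, 3L,
                 2L, 4L, 2L, 4L), 4, 4, byrow = TRUE)
  szm <- build_texture_matrices(labeled_from_grid(g3))$glszm
  expect_equal(ncol(szm), 1)   # all zones size 1
  expect_equal(sum(szm), 16)
  expect_equal(szm, oracle_glszm(g3, 4))
})

test_that("GLCM symmetry and marginal-sum invariants hold", {
  set.seed(8)
  for (rep in 1:20) {
    g <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    if (sum(g > 0) < 2) next
    mats <- build_texture_matrices(
      structure(list(labels = g, n_levels = 3L, n_pixels = sum(g > 0)),
                class = "labeled_roi"))
    expect_equal(mats$glcm, t(mats$glcm))
    expect_equal(mats$glcm, oracle_glcm(g, 3))
    expect_equal(sum(mats$glrlm %*% seq_len(ncol(mats$glrlm))),
                 4 * sum(g > 0))                                   # runs cover pixels
    expect_equal(sum(mats$glszm %*% seq_len(ncol(mats$glszm))),
                 sum(g > 0))                                       # zones cover pixels
  }
})

test_that("degenerate texture features take their guarded values", {
  # single-cell GLCM: info.corr.2 = 0 and correlation guard engages
  g <- matrix(1L, 3, 3)
  f <- texture_features(build_texture_matrices(labeled_from_grid(g)))
  expect_equal(unname(f["F_cm.info.corr.2"]), 0)
  expect_equal(unname(f["F_rlm.glnu.norm"]), 1)  # single level
  expect_equal(unname(f["F_szm.glu.norm"]), 1)
})

test_that("hand-written two-level grid matches brute-force pair enumeration", {
  g <- matrix(c(1L, 2L, 2L, 1L,
                1L, 1L, 2L, 2L,
                2L, 1L, 1L, 2L,
                1L, 2L, 1L, 1L), 4, 4, byrow = TRUE)
  mats <- build_texture_matrices(labeled_from_grid(g))
  expect_equal(mats$glcm, oracle_glcm(g, 2), tolerance = 1e-12)
  expect_equal(mats$glrlm, oracle_glrlm(g, 2), tolerance = 1e-12)
  expect_equal(mats$glszm, oracle_glszm(g, 2), tolerance = 1e-12)
  f1 <- texture_features(mats)
  mats_o <- mats
  mats_o$glcm <- oracle_glcm(g, 2)
  mats_o$glrlm <- oracle_glrlm(g, 2)
  mats_o$glszm <- oracle_glszm(g, 2)
  expect_equal(texture_features(mats_o), f1, tolerance = 1e-12)
})

test_that("extraction is deterministic, complete and affine-invariant", {
  cs <- make_test_case(seed = 21, texture_amp = 0.5)
  f1 <- extract_features(cs)
  f2 <- extract_features(cs)
  expect_identical(f1, f2)
  expect_length(f1, 74)
  expect_false(anyNA(f1))
  expect_identical(names(f1), feature_registry())

  cs2 <- cs
  cs2$image <- cs$image * 1.7 + 12
  expect_equal(unclass(extract_features(cs2))[], unclass(f1)[], tolerance = 1e-8)
})

test_that("direction-merged features are invariant to image transpose", {
  cs <- make_test_case(seed = 22)
  cs_t <- list(case_id = cs$case_id, image = t(cs$image), mask = t(cs$mask))
  f <- extract_features(cs)
  ft <- extract_features(cs_t)
  expect_equal(unclass(f)[], unclass(ft)[], tolerance = 1e-10)
})

test_that("malignant-class kurtosis exceeds benign at the default effect size", {
  coh <- generate_cohort(cohort_spec(80, seed = 31, image_size = 64))
  fm <- extract_feature_matrix(coh)
  y <- is_malignant(cohort_outcomes(coh))
  expect_gt(mean(fm[y, "F.stat.kurt"]), mean(fm[!y, "F.stat.kurt"]))
})
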