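# Feature screening, multiplicity adjustment, redundancy pruning, frozen
# scaling and the MRMR/RFE alternates.

test_that("the Mann-Whitney screen reproduces the exact permutation p-value", {
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  p <- mwu_screen(x, y)
  expect_equal(unname(p), 0.1, tolerance = 1e-12)  # 2 / choose(6,3) extreme tables
  # label swap symmetry
  expect_equal(unname(mwu_screen(x, !y)), unname(p), tolerance = 1e-12)
  expect_error(mwu_screen(x, rep(TRUE, 6)), "class")
})

test_that("null p-values are uniform and raw rejections track alpha", {
  set.seed(14)
  x <- matrix(rnorm(1000 * 74), 1000, 74,
              dimnames = list(NULL, feature_registry()))
  y <- rep(c(TRUE, FALSE), each = 500)
  p <- mwu_screen(x, y)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.06)  # ~ alpha * 74 rejections
})

test_that("BH adjustment follows the step-up thresholds", {
  out <- bh_adjust(c(a = 0.01, b = 0.02, c = 0.04), alpha = 0.05)
  expect_identical(out$significant, c("a", "b", "c"))
  expect_equal(unname(out$adjusted_p), c(0.03, 0.03, 0.04))
  # all ones
  out1 <- bh_adjust(rep(1, 5))
  expect_length(out1$significant, 0)
  expect_true(all(out1$adjusted_p == 1))
  # m = 1 identity
  expect_equal(unname(bh_adjust(0.03)$adjusted_p), 0.03)
  # adjusted >= raw, elementwise
  set.seed(3)
  p <- runif(40)
  expect_true(all(bh_adjust(p)$adjusted_p >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the reference step-up implementation", {
  set.seed(4)
  for (rep in 1:50) {
    p <- runif(sample(2:60, 1))^sample(1:3, 1)
    expect_lt(max(abs(bh_adjust(p)$adjusted_p - p.adjust(p, "BH"))), 1e-12)
  }
})

test_that("correlated features are pruned greedily by ascending p", {
  set.seed(6)
  base <- rnorm(60)
  x <- cbind(f1 = base + rnorm(60, sd = 0.1),
             f2 = base + rnorm(60, sd = 0.1),
             f3 = rnorm(60))
  p <- c(f1 = 0.001, f2 = 0.01, f3 = 0.02)
  kept <- prune_correlated(x, c("f1", "f2", "f3"), p, threshold = 0.6)
  expect_identical(kept, c("f1", "f3"))  # f2 dropped: |r(f1,f2)| > 0.6

  # nothing correlated: all kept, ordered by p
  x2 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  p2 <- c(a = 0.5, b = 0.001, c = 0.2)
  expect_identical(prune_correlated(x2, colnames(x2), p2), c("b", "c", "a"))
})

test_that("pruning a correlation chain equals a direct replay of the greedy rule", {
  set.seed(7)
  n <- 80
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- cbind(g1 = z1,
             g2 = z1 * 0.9 + rnorm(n, sd = 0.4),
             g3 = z1 * 0.5 + z2 * 0.8,
             g4 = z2 + rnorm(n, sd = 0.3),
             g5 = rnorm(n))
  p <- c(g1 = 0.004, g2 = 0.001, g3 = 0.01, g4 = 0.002, g5 = 0.03)
  kept <- prune_correlated(x, colnames(x), p, threshold = 0.6)
  # independent replay: order by p, accept iff max |r| with accepted <= 0.6
  ord <- names(sort(p))
  acc <- character(0)
  for (f in ord) {
    r <- if (length(acc)) max(abs(cor(x[, f], x[, acc]))) else 0
    if (r <= 0.6) acc <- c(acc, f)
  }
  expect_identical(kept, acc)
  # invariance to column permutation
  perm <- c("g5", "g3", "g1", "g4", "g2")
  expect_setequal(prune_correlated(x[, perm], perm, p), kept)
})

test_that("the frozen scaler standardizes train and transports to validation", {
  train <- cbind(f = c(2, 4, 6))
  sc <- fit_scaler(train)
  expect_equal(as.numeric(apply_scaler(sc, train)), c(-1, 0, 1))
  expect_equal(as.numeric(apply_scaler(sc, cbind(f = 8))), 2)
  big <- matrix(rnorm(200, 5, 3), 50, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
  sc2 <- fit_scaler(big)
  scaled <- apply_scaler(sc2, big)
  expect_equal(unname(colMeans(scaled)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(scaled, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # reapplication is NOT idempotent unless the scaler is the identity
  expect_false(isTRUE(all.equal(apply_scaler(sc2, scaled), scaled)))
  expect_error(fit_scaler(cbind(f = rep(3, 5))), "zero-SD")
})

test_that("MRMR and RFE keep everything at k = n and find a dominant signal at k = 1", {
  set.seed(9)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(signal = y + rnorm(n, sd = 0.1),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  expect_setequal(mrmr_select(x, y, 4), colnames(x))
  expect_setequal(rfe_select(x, y, 4), colnames(x))
  expect_identical(mrmr_select(x, y, 1), "signal")
  expect_identical(rfe_select(x, y, 1), "signal")
  expect_error(mrmr_select(x, y, 0), "range")
  expect_error(rfe_select(x, y, 9), "range")
})

test_that("MRMR matches a hand replay of its greedy objective", {
  set.seed(10)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  base <- y + rnorm(n, sd = 0.5)
  x <- cbind(a = base,
             b = base + rnorm(n, sd = 0.2),   # redundant with a
             c = y + rnorm(n, sd = 1.5),
             d = rnorm(n),
             e = -base + rnorm(n, sd = 0.3),  # anti-correlated duplicate
             f = rnorm(n))
  k <- 3
  got <- mrmr_select(x, y, k)
  # replay
  rel <- abs(apply(x, 2, cor, y = y))
  sel <- names(which.max(rel))
  while (length(sel) < k) {
    rest <- setdiff(colnames(x), sel)
    sc <- sapply(rest, function(fn)
      rel[fn] - mean(abs(cor(x[, fn], x[, sel, drop = FALSE]))))
    sel <- c(sel, rest[which.max(sc)])
  }
  expect_identical(got, sel)
})

test_that("the full cascade composes and reports consistently", {
  set.seed(11)
  coh <- generate_cohort(cohort_spec(100, seed = 12, image_size = 64))
  fm <- extract_feature_matrix(coh)
  y <- is_malignant(cohort_outcomes(coh))
  sel <- select_features(fm, y)
  expect_s3_class(sel, "selection_result")
  expect_true(all(sel$kept %in% sel$significant))
  expect_true(all(sel$significant %in% feature_registry()))
  expect_true(all(sel$adjusted_p >= sel$p_values - 1e-15))
  # kept features are pairwise below the threshold
  if (length(sel$kept) > 1) {
    cm <- abs(cor(fm[, sel$kept]))
    diag(cm) <- 0
    expect_lte(max(cm), 0.6)
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  expect_identical(jsonlite::read_json(path, simplifyVector = TRUE)$kept, sel$kept)
})
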