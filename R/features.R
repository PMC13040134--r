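# IBSI-style 2-D radiomics features from a Z-score-normalized ROI.
#
# The registry holds exactly 74 named features: 17 intensity statistics,
# 25 gray-level co-occurrence (GLCM), 16 run-length (GLRLM) and 16
# size-zone (GLSZM) features. Texture families are computed from merged
# (direction-summed) matrices over the four 2-D directions at distance 1;
# GLSZM zones are 8-connected and direction-free. Gray levels come from
# fixed-bin-number discretization of the ROI Z-scores (default 32 bins).

.stat_names <- paste0("F.stat.", c(
  "mean", "var", "skew", "kurt", "median", "min", "max", "p10", "p90",
  "iqr", "range", "mad", "medad", "energy", "rms", "entropy", "unif"))

.glcm_names <- paste0("F_cm.", c(
  "joint.max", "joint.avg", "joint.var", "joint.entr",
  "diff.avg", "diff.var", "diff.entr",
  "sum.avg", "sum.var", "sum.entr",
  "energy", "contrast", "dissimilarity",
  "inv.diff", "inv.diff.norm", "inv.diff.mom", "inv.diff.mom.norm",
  "inv.var", "corr", "auto.corr",
  "clust.tend", "clust.shade", "clust.prom",
  "info.corr.1", "info.corr.2"))

.glrlm_names <- paste0("F_rlm.", c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "glnu.norm", "rlnu", "rlnu.norm", "r.perc",
  "gl.var", "rl.var", "rl.entr"))

.glszm_names <- paste0("F_szm.", c(
  "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
  "glnu", "glu.norm", "zsnu", "zsnu.norm", "z.perc",
  "gl.var", "zs.var", "zs.entr"))

#' The radiomics feature registry
#'
#' @return character vector of the 74 feature names, in canonical order:
#'   intensity statistics (`F.stat.*`), co-occurrence (`F_cm.*`),
#'   run-length (`F_rlm.*`) and size-zone (`F_szm.*`) features.
#' @export
feature_registry <- function() {
  c(.stat_names, .glcm_names, .glrlm_names, .glszm_names)
}

#' Fixed-bin-number discretization of a normalized ROI
#'
#' Equal-width bins spanning `[min, max]` of the ROI Z-scores, right-closed
#' (a value on an interior bin edge falls in the lower bin; the minimum is
#' assigned label 1, the maximum label `n_bins`).
#'
#' @param roi a [zscore_roi()] result.
#' @param n_bins number of gray levels, >= 2 (default 32).
#' @return object of class `labeled_roi`: list with `labels` (integer
#'   matrix, 0 outside the mask, 1..n_bins inside), `n_levels`, `n_pixels`.
#' @export
discretize <- function(roi, n_bins = 32) {
  stopifnot(inherits(roi, "normalized_roi"))
  if (n_bins < 2) stopf("n_bins must be >= 2, got %s", n_bins)
  v <- roi$values
  w <- (max(v) - min(v)) / n_bins
  lab <- ceiling((v - min(v)) / w)
  lab[lab < 1L] <- 1L
  lab[lab > n_bins] <- n_bins
  labels <- matrix(0L, nrow(roi$zmat), ncol(roi$zmat))
  labels[roi$mask == 1] <- as.integer(lab)
  structure(list(labels = labels, n_levels = as.integer(n_bins),
                 n_pixels = length(v)),
            class = "labeled_roi")
}

#' Intensity-based statistical features of a normalized ROI
#'
#' Mean, variance, skewness and excess kurtosis use population moments
#' (kurtosis = mu4/mu2^2 - 3); percentiles use the default quantile
#' definition; `medad` is the unscaled median absolute deviation from the
#' median; histogram entropy and uniformity use the same fixed-bin-number
#' discretization as the texture families.
#'
#' @param roi a [zscore_roi()] result.
#' @param n_bins bins for the histogram entropy/uniformity (default 32).
#' @return named numeric vector of the 17 `F.stat.*` features.
#' @export
intensity_statistics <- function(roi, n_bins = 32) {
  v <- roi$values
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  q <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  p <- tabulate(discretize(roi, n_bins)$labels, nbins = n_bins) / n
  p <- p[p > 0]
  out <- c(
    mu, m2,
    m3 / m2^1.5, m4 / m2^2 - 3,
    median(v), min(v), max(v), q[1], q[4],
    q[3] - q[2], max(v) - min(v),
    mean(abs(v - mu)),
    median(abs(v - median(v))),
    sum(v^2), sqrt(mean(v^2)),
    -sum(p * log2(p)), sum(p^2)
  )
  names(out) <- .stat_names
  out
}

#' Texture matrices of a discretized ROI
#'
#' GLCM: distance-1 pixel pairs over the four 2-D directions (0, 45, 90,
#' 135 degrees), counted only when both pixels are inside the mask,
#' symmetrized and summed over directions. GLRLM: maximal same-level runs
#' per direction, summed over the four directions. GLSZM: 8-connected
#' constant-level zones (direction-free).
#'
#' @param labeled a [discretize()] result.
#' @return object of class `texture_matrices`: list with `glcm` (Ng x Ng),
#'   `glrlm` (Ng x max run length), `glszm` (Ng x max zone size) count
#'   matrices and `n_pixels`.
#' @export
build_texture_matrices <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_roi"))
  structure(list(
    glcm = .glcm_counts_cpp(labeled$labels, labeled$n_levels),
    glrlm = .glrlm_counts_cpp(labeled$labels, labeled$n_levels),
    glszm = .glszm_counts_cpp(labeled$labels, labeled$n_levels),
    n_pixels = labeled$n_pixels
  ), class = "texture_matrices")
}

#' Texture features from GLCM/GLRLM/GLSZM matrices
#'
#' Implements the IBSI definitions for the 25 co-occurrence, 16 run-length
#' and 16 size-zone features in the registry. All entropies are in bits.
#' The second measure of information correlation is
#' `sqrt(1 - exp(-2 (HXY2 - HXY)))`, guarded at 0 when `HXY2 < HXY`; the
#' normalized gray-level non-uniformities are `sum_i (sum_j m_ij)^2 / N^2`
#' with `N` the total run/zone count.
#'
#' @param mats a [build_texture_matrices()] result.
#' @return named numeric vector of the 57 texture features.
#' @export
texture_features <- function(mats) {
  stopifnot(inherits(mats, "texture_matrices"))
  if (sum(mats$glcm) == 0 || sum(mats$glrlm) == 0 || sum(mats$glszm) == 0)
    stopf("texture_features: empty texture matrix")
  c(glcm_features(mats$glcm),
    rl_sz_features(mats$glrlm, mats$n_pixels, run_dirs = 4, prefix = "F_rlm.",
                   feat = c("sre", "lre", "lgre", "hgre", "srlge", "srhge",
                            "lrlge", "lrhge", "glnu", "glnu.norm", "rlnu",
                            "rlnu.norm", "r.perc", "gl.var", "rl.var",
                            "rl.entr")),
    rl_sz_features(mats$glszm, mats$n_pixels, run_dirs = 1, prefix = "F_szm.",
                   feat = c("sze", "lze", "lgze", "hgze", "szlge", "szhge",
                            "lzlge", "lzhge", "glnu", "glu.norm", "zsnu",
                            "zsnu.norm", "z.perc", "gl.var", "zs.var",
                            "zs.entr")))
}

glcm_features <- function(counts) {
  ng <- nrow(counts)
  p <- counts / sum(counts)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_ <- rowSums(p)                     # = colSums(p): symmetric
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  # difference and sum marginal distributions
  dvals <- 0:(ng - 1)
  pd <- vapply(dvals, function(k) sum(p[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * ng)
  ps <- vapply(svals, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(dvals * pd)
  sa <- sum(svals * ps)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  hx <- ent(pi_)
  prod_marg <- outer(pi_, pi_)
  pos <- p > 0 & prod_marg > 0
  hxy1 <- -sum(p[pos] * log2(prod_marg[pos]))
  hxy2 <- ent(prod_marg)
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- if (hxy2 > hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  out <- c(
    max(p), mu, sig2, hxy,
    da, sum((dvals - da)^2 * pd), ent(pd),
    sa, sum((svals - sa)^2 * ps), ent(ps),
    sum(p^2), sum((i - j)^2 * p), sum(abs(i - j) * p),
    sum(p / (1 + abs(i - j))), sum(p / (1 + abs(i - j) / ng)),
    sum(p / (1 + (i - j)^2)), sum(p / (1 + (i - j)^2 / ng^2)),
    sum(p[i != j] / (i - j)[i != j]^2),
    corr, sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p), sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    ic1, ic2
  )
  names(out) <- .glcm_names
  out
}

# shared run-length / size-zone feature formulas; `run_dirs` is the number
# of scanning directions merged into the matrix (4 for runs, 1 for zones),
# entering only the run/zone percentage denominator
rl_sz_features <- function(m, n_pixels, run_dirs, prefix, feat) {
  ns <- sum(m)
  p <- m / ns
  gi <- rowSums(m)                      # per-level counts
  rj <- colSums(m)                      # per-length/size counts
  iv <- seq_len(nrow(m))
  jv <- seq_len(ncol(m))
  imat <- matrix(iv, nrow(m), ncol(m))
  jmat <- matrix(jv, nrow(m), ncol(m), byrow = TRUE)
  mu_i <- sum(imat * p)
  mu_j <- sum(jmat * p)
  pp <- p[p > 0]
  out <- c(
    sum(rj / jv^2) / ns, sum(rj * jv^2) / ns,
    sum(gi / iv^2) / ns, sum(gi * iv^2) / ns,
    sum(m / (imat^2 * jmat^2)) / ns, sum(m * imat^2 / jmat^2) / ns,
    sum(m * jmat^2 / imat^2) / ns, sum(m * imat^2 * jmat^2) / ns,
    sum(gi^2) / ns, sum(gi^2) / ns^2,
    sum(rj^2) / ns, sum(rj^2) / ns^2,
    ns / (run_dirs * n_pixels),
    sum((imat - mu_i)^2 * p), sum((jmat - mu_j)^2 * p),
    -sum(pp * log2(pp))
  )
  names(out) <- paste0(prefix, feat)
  out
}

#' Extract the full 74-feature vector from an ultrasound case
#'
#' Composition of the fixed preprocessing and feature pipeline: adaptive
#' Wiener despeckling of the full image, per-ROI Z-score normalization,
#' fixed-bin-number discretization, texture-matrix construction, and the
#' complete feature registry. Deterministic.
#'
#' @param case an `ultrasound_case` (or a list with `image`, `mask` and
#'   optionally `case_id`).
#' @param n_bins gray levels for discretization (default 32).
#' @param kernel Wiener window size (default 3).
#' @return named numeric vector of the 74 registry features, with
#'   attributes `case_id` and `n_bins`.
#' @export
extract_features <- function(case, n_bins = 32, kernel = 3) {
  img <- wiener_despeckle(case$image, kernel = kernel)
  roi <- zscore_roi(img, case$mask, case_id = case$case_id)
  labeled <- discretize(roi, n_bins = n_bins)
  mats <- build_texture_matrices(labeled)
  out <- c(intensity_statistics(roi, n_bins = n_bins), texture_features(mats))
  stopifnot(identical(names(out), feature_registry()))
  attr(out, "case_id") <- case$case_id
  attr(out, "n_bins") <- n_bins
  out
}

#' Extract the feature matrix of a whole cohort
#'
#' @param cohort a `us_cohort`.
#' @inheritParams extract_features
#' @return numeric matrix, cases x 74 features, rownames = case ids, with
#'   attribute `n_bins`.
#' @export
extract_feature_matrix <- function(cohort, n_bins = 32, kernel = 3) {
  rows <- lapply(cohort, function(cs) {
    f <- extract_features(cs, n_bins = n_bins, kernel = kernel)
    attributes(f) <- list(names = names(f))
    f
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(cohort, `[[`, character(1), "case_id")
  attr(mat, "n_bins") <- n_bins
  mat
}
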