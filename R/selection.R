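# Feature selection: Mann-Whitney screen -> Benjamini-Hochberg adjustment
# -> greedy Pearson redundancy pruning, with MRMR and RFE alternates.
# Everything is fit on the training split only; the frozen Z-scaler makes
# leakage-free application to validation data explicit.

#' Mann-Whitney U screen of a feature matrix
#'
#' Two-tailed p-value per feature for a location difference between the
#' two outcome classes. Exact when both groups have <= 8 cases and no
#' ties; otherwise the normal approximation with tie and continuity
#' correction (via [stats::wilcox.test()]).
#'
#' @param x numeric matrix, cases x features.
#' @param labels logical or 0/1 vector, `TRUE`/1 = malignant.
#' @return named numeric vector of p-values.
#' @export
mwu_screen <- function(x, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stopf("mwu_screen: both classes required")
  if (sum(labels) < 2 || sum(!labels) < 2)
    stopf("mwu_screen: both classes need >= 2 cases")
  apply(x, 2, function(col) {
    a <- col[labels]; b <- col[!labels]
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: adjusted p for the i-th
#' smallest p-value is `min_{k >= i} (m/k) p_(k)`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level for the `significant` set (default 0.05).
#' @return list with `adjusted_p` (same order and names as `p`) and
#'   `significant` (names, or indices when `p` is unnamed, with adjusted
#'   p <= alpha).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("bh_adjust: p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))          # monotonicity enforcement, step-up
  adj <- pmin(adj, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj
  names(adjusted) <- names(p)
  ids <- if (is.null(names(p))) which(adjusted <= alpha) else names(p)[adjusted <= alpha]
  list(adjusted_p = adjusted, significant = ids)
}

#' Greedy Pearson redundancy pruning
#'
#' Orders the significant features by ascending screen p-value (ties broken
#' by registry order, i.e. column order of `x`) and accepts a feature iff
#' its absolute Pearson correlation with every already-accepted feature is
#' at most `threshold` on the training set; when two features are too
#' correlated the one with the lower p-value therefore survives.
#'
#' @param x training feature matrix (raw scale).
#' @param significant names of the features that passed the adjusted screen.
#' @param p_values named screen p-values (at least for `significant`).
#' @param threshold maximum tolerated absolute correlation (default 0.6).
#' @return character vector of kept features, in acceptance order.
#' @export
prune_correlated <- function(x, significant, p_values, threshold = 0.6) {
  if (length(significant) == 0) stopf("prune_correlated: no significant features")
  zero_var <- significant[apply(x[, significant, drop = FALSE], 2, sd) == 0]
  if (length(zero_var) > 0) {
    warning("excluding zero-variance feature(s): ",
            paste(zero_var, collapse = ", "))
    significant <- setdiff(significant, zero_var)
  }
  ord <- significant[order(p_values[significant],
                           match(significant, colnames(x)))]
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0 ||
        all(abs(cor(x[, f], x[, kept, drop = FALSE])) <= threshold))
      kept <- c(kept, f)
  }
  kept
}

#' Frozen Z-score scaling of features
#'
#' Per-feature standardization with mean and sample SD estimated on the
#' training matrix only; the returned scaler is then applied unchanged to
#' any other matrix (validation, new cases).
#'
#' @param train training feature matrix.
#' @return object of class `feature_scaler` with `center`, `scale` and
#'   `features`; apply it with [apply_scaler()].
#' @export
fit_scaler <- function(train) {
  ctr <- colMeans(train, na.rm = TRUE)
  scl <- apply(train, 2, sd, na.rm = TRUE)
  if (any(scl == 0))
    stopf("zero-SD feature(s): %s",
          paste(colnames(train)[scl == 0], collapse = ", "))
  structure(list(center = ctr, scale = scl, features = colnames(train)),
            class = "feature_scaler")
}

#' Apply a frozen feature scaler
#' @param scaler a [fit_scaler()] result.
#' @param x matrix with (at least) the scaler's features as columns.
#' @return scaled matrix restricted to the scaler's features.
#' @export
apply_scaler <- function(scaler, x) {
  missing_f <- setdiff(scaler$features, colnames(x))
  if (length(missing_f) > 0)
    stopf("apply_scaler: missing feature(s): %s", paste(missing_f, collapse = ", "))
  x <- x[, scaler$features, drop = FALSE]
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy forward selection maximizing the absolute point-biserial
#' correlation with the class label minus the mean absolute Pearson
#' correlation with the already-selected set.
#'
#' @param x training feature matrix.
#' @param labels logical/0-1 outcome.
#' @param k number of features to keep.
#' @return character vector of `k` selected features, in selection order.
#' @export
mrmr_select <- function(x, labels, k) {
  if (k < 1 || k > ncol(x)) stopf("mrmr_select: k out of range")
  y <- as.numeric(labels)
  relevance <- abs(apply(x, 2, function(col) suppressWarnings(cor(col, y))))
  relevance[is.na(relevance)] <- 0
  selected <- names(which.max(relevance))
  while (length(selected) < k) {
    rest <- setdiff(colnames(x), selected)
    score <- vapply(rest, function(f) {
      red <- mean(abs(suppressWarnings(
        cor(x[, f], x[, selected, drop = FALSE]))), na.rm = TRUE)
      if (is.na(red)) red <- 0
      relevance[f] - red
    }, numeric(1))
    selected <- c(selected, rest[which.max(score)])
  }
  selected
}

#' Recursive feature elimination
#'
#' Iteratively refits a gradient-boosted-tree model and drops the feature
#' with the lowest gain importance until `k` features remain.
#'
#' @inheritParams mrmr_select
#' @param seed RNG seed for the refits.
#' @param nrounds,max_depth fixed booster settings for the eliminator.
#' @return character vector of the `k` surviving features.
#' @export
rfe_select <- function(x, labels, k, seed = 1, nrounds = 50, max_depth = 3) {
  if (k < 1 || k > ncol(x)) stopf("rfe_select: k out of range")
  keep <- colnames(x)
  y <- as.numeric(labels)
  while (length(keep) > k) {
    bst <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = max_depth),
      data = xgboost::xgb.DMatrix(x[, keep, drop = FALSE], label = y,
                                  nthread = 1),
      nrounds = nrounds, verbose = 0))
    dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
    splits <- dump[dump$Feature != "Leaf", c("Feature", "Gain")]
    gain <- stats::setNames(rep(0, length(keep)), keep)
    agg <- tapply(splits$Gain, splits$Feature, sum)
    gain[names(agg)] <- agg
    keep <- setdiff(keep, names(which.min(gain)))
  }
  keep
}

#' Full feature-selection cascade
#'
#' The default method screens every feature with the Mann-Whitney U test,
#' adjusts for multiplicity with Benjamini-Hochberg (alpha = 0.05), and
#' prunes redundant survivors by greedy absolute-Pearson thresholding
#' (|r| <= 0.6, lower p wins). `"mrmr"` and `"rfe"` are the alternates used
#' when the primary cascade overfits.
#'
#' @param x training feature matrix (raw scale).
#' @param labels logical/0-1 outcome (TRUE = malignant).
#' @param method one of `"mwu_bh_pearson"`, `"mrmr"`, `"rfe"`.
#' @param alpha BH significance level.
#' @param r_threshold Pearson pruning threshold.
#' @param k number of features for the MRMR/RFE alternates.
#' @param seed RNG seed (RFE refits).
#' @return object of class `selection_result` with `p_values`,
#'   `adjusted_p`, `significant`, `kept`, `method` and the thresholds.
#' @export
select_features <- function(x, labels, method = c("mwu_bh_pearson", "mrmr", "rfe"),
                            alpha = 0.05, r_threshold = 0.6, k = 14, seed = 1) {
  method <- match.arg(method)
  p <- mwu_screen(x, labels)
  bh <- bh_adjust(p, alpha = alpha)
  kept <- switch(method,
    mwu_bh_pearson = prune_correlated(x, bh$significant, p, threshold = r_threshold),
    mrmr = mrmr_select(x, labels, k),
    rfe = rfe_select(x, labels, k, seed = seed))
  structure(list(
    p_values = p,
    adjusted_p = bh$adjusted_p,
    significant = bh$significant,
    kept = kept,
    method = method,
    alpha = alpha,
    r_threshold = r_threshold
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> method %s: %d/%d significant (BH alpha %.2f), %d kept (|r| <= %.2f)\n",
    x$method, length(x$significant), length(x$p_values), x$alpha,
    length(x$kept), x$r_threshold))
  cat("kept:", paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param sel a `selection_result`.
#' @param path output file.
#' @return (invisibly) `path`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(unclass(sel), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
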