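# Validation battery: discrimination (AUC with stratified bootstrap CI,
# DeLong comparison), classification metrics at clinical and Youden
# cutoffs, logistic recalibration, decision-curve analysis, SHAP-based
# overfitting scores, and the manufacturer PCA diagnostic.

#' Point estimate of the area under the ROC curve
#'
#' Rank (concordance) identity with ties counted 1/2, i.e. the
#' Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param risks numeric predicted risks.
#' @param labels logical or 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc_estimate <- function(risks, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("auc: both classes must be present")
  r <- rank(risks)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with stratified bootstrap confidence interval
#'
#' Percentile CI from `n_boot` stratified resamples (cases resampled
#' within outcome class), seeded.
#'
#' @inheritParams auc_estimate
#' @param n_boot bootstrap resamples, default 2000.
#' @param conf confidence level, default 0.95.
#' @param seed RNG seed.
#' @return object of class `auc_ci`: list with `auc`, `ci` (length 2),
#'   `conf`, `n_boot`.
#' @export
auc_ci <- function(risks, labels, n_boot = 2000, conf = 0.95, seed = 1) {
  labels <- as.logical(labels)
  est <- auc_estimate(risks, labels)
  pos <- which(labels); neg <- which(!labels)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc_estimate(risks[idx], labels[idx])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  structure(list(auc = est,
                 ci = unname(quantile(boot, c(alpha, 1 - alpha))),
                 conf = conf, n_boot = n_boot),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI, %.3f-%.3f; %d bootstrap resamples)\n",
              x$auc, round(100 * x$conf), x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

# DeLong placement components: for each positive case the fraction of
# negatives it beats (ties 1/2), and vice versa
delong_placements <- function(risks, labels) {
  x <- risks[labels]; y <- risks[!labels]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for the difference between two paired AUCs
#'
#' Both risk vectors must score the same cases. The variance of the AUC
#' difference is estimated from the empirical covariance of the DeLong
#' placement values; the p-value is two-sided normal.
#'
#' @param risks_a,risks_b paired predicted risks.
#' @param labels logical/0-1 outcomes.
#' @return list with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p_value`.
#' @export
delong_compare <- function(risks_a, risks_b, labels) {
  if (length(risks_a) != length(risks_b) || length(risks_a) != length(labels))
    stopf("delong_compare: inputs must be paired predictions on identical cases")
  labels <- as.logical(labels)
  pa <- delong_placements(risks_a, labels)
  pb <- delong_placements(risks_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  l <- c(1, -1)
  v <- drop(t(l) %*% (s10 / m + s01 / n) %*% l)
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d,
       se = sqrt(max(v, 0)), z = z, p_value = 2 * pnorm(-abs(z)))
}

# normal-approximation CI for a proportion; NA bounds when the cell is empty
prop_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  p <- k / n
  half <- qnorm(1 - (1 - conf) / 2) * sqrt(p * (1 - p) / n)
  c(p, p - half, p + half)
}

#' Classification metrics at a fixed risk cutoff
#'
#' A case is classified malignant iff `risk >= cutoff`. Proportion CIs use
#' the normal approximation `p +/- z * sqrt(p (1-p) / n)`; likelihood-ratio
#' CIs use the log method. Metrics whose denominator class is empty are
#' reported with `NA` intervals.
#'
#' @param risks predicted risks.
#' @param labels logical/0-1 outcomes.
#' @param cutoff risk cutoff in (0, 1); default the 10% clinical referral
#'   threshold.
#' @param conf confidence level.
#' @return object of class `classification_metrics`: list of
#'   `c(estimate, lower, upper)` triplets for sensitivity, specificity,
#'   ppv, npv, accuracy, lr_pos, lr_neg, plus the confusion counts.
#' @export
metrics_at_cutoff <- function(risks, labels, cutoff = 0.10, conf = 0.95) {
  if (cutoff <= 0 || cutoff >= 1) stopf("cutoff must be in (0, 1)")
  labels <- as.logical(labels)
  pred <- risks >= cutoff
  tp <- sum(pred & labels);  fn <- sum(!pred & labels)
  fp <- sum(pred & !labels); tn <- sum(!pred & !labels)
  sens <- prop_ci(tp, tp + fn, conf)
  spec <- prop_ci(tn, tn + fp, conf)
  z <- qnorm(1 - (1 - conf) / 2)
  lr_ci <- function(lr, a, n1, b, n2) {
    # log-method SE for a ratio of two proportions a/n1 over b/n2
    if (!is.finite(lr) || lr <= 0 || a == 0 || b == 0)
      return(c(lr, NA_real_, NA_real_))
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
    c(lr, exp(log(lr) - z * se), exp(log(lr) + z * se))
  }
  lr_pos <- if (spec[1] < 1) sens[1] / (1 - spec[1]) else Inf
  lr_neg <- if (spec[1] > 0) (1 - sens[1]) / spec[1] else Inf
  structure(list(
    cutoff = cutoff,
    sensitivity = sens, specificity = spec,
    ppv = prop_ci(tp, tp + fp, conf),
    npv = prop_ci(tn, tn + fn, conf),
    accuracy = prop_ci(tp + tn, tp + fn + fp + tn, conf),
    lr_pos = lr_ci(lr_pos, tp, tp + fn, fp, fp + tn),
    lr_neg = lr_ci(lr_neg, fn, tp + fn, tn, fp + tn),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("classification at cutoff %.0f%%\n", 100 * x$cutoff))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv",
              "lr_pos", "lr_neg")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %.2f (%.2f-%.2f)\n", m, v[1], v[2], v[3]))
  }
  invisible(x)
}

#' Optimal cutoff by Youden's index
#'
#' Evaluates `J = sensitivity + specificity - 1` with positivity defined as
#' `risk >= cutoff` at every distinct risk value and returns the maximizer;
#' ties are broken toward the lowest cutoff (which maximizes sensitivity).
#'
#' @inheritParams metrics_at_cutoff
#' @return list with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(risks, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("youden_cutoff: both classes required")
  cand <- sort(unique(risks))
  n1 <- sum(labels); n0 <- sum(!labels)
  best <- list(cutoff = cand[1], j = -Inf)
  for (ct in cand) {
    pred <- risks >= ct
    j <- sum(pred & labels) / n1 + sum(!pred & !labels) / n0 - 1
    if (j > best$j) best <- list(cutoff = ct, j = j)  # strict: ties keep lowest
  }
  pred <- risks >= best$cutoff
  list(cutoff = best$cutoff, j = best$j,
       sensitivity = sum(pred & labels) / n1,
       specificity = sum(!pred & !labels) / n0)
}

#' Calibration intercept, slope and smoothed curve
#'
#' Logistic recalibration: the slope is the coefficient of a single-
#' predictor logistic regression of the outcome on `logit(risk)`; the
#' intercept is the intercept of a logistic regression with `logit(risk)`
#' as a fixed offset. Predicted risks that are, on average, systematically
#' underestimated give intercept > 0 (overestimated: < 0); risks that are
#' too extreme give slope < 1. The curve is a local-linear (tricube-
#' weighted) smoother of outcomes against predicted risk on an even grid,
#' bandwidth 0.3 of the observed risk range.
#'
#' @inheritParams metrics_at_cutoff
#' @param grid_size number of curve points (default 50).
#' @param conf confidence level for intercept/slope Wald CIs.
#' @return object of class `calibration_result`: `intercept` and `slope`
#'   as `c(estimate, lower, upper)`, `curve` (data.frame `predicted`,
#'   `observed`) and `converged`.
#' @export
calibration <- function(risks, labels, grid_size = 50, conf = 0.95) {
  labels <- as.numeric(as.logical(labels))
  r <- pmin(pmax(risks, 1e-6), 1 - 1e-6)
  lp <- qlogis(r)
  if (sd(lp) == 0) stopf("calibration: constant risks, slope undefined")
  z <- qnorm(1 - (1 - conf) / 2)
  fit_slope <- glm(labels ~ lp, family = binomial())
  fit_int <- glm(labels ~ 1 + offset(lp), family = binomial())
  sl <- summary(fit_slope)$coefficients["lp", 1:2]
  ic <- summary(fit_int)$coefficients["(Intercept)", 1:2]
  grid <- seq(min(r), max(r), length.out = grid_size)
  bw <- 0.3 * (max(r) - min(r))
  observed <- vapply(grid, function(g) {
    w <- (1 - pmin(abs(r - g) / bw, 1)^3)^3
    if (sum(w > 0) < 2 || sum(w) == 0) return(NA_real_)
    fit <- stats::lm.wfit(cbind(1, r - g), labels, w)
    fit$coefficients[1]
  }, numeric(1))
  structure(list(
    intercept = c(ic[1], ic[1] - z * ic[2], ic[1] + z * ic[2]),
    slope = c(sl[1], sl[1] - z * sl[2], sl[1] + z * sl[2]),
    curve = data.frame(predicted = grid, observed = observed),
    converged = fit_slope$converged && fit_int$converged
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration intercept %.2f (%.2f to %.2f), slope %.2f (%.2f to %.2f)\n",
              x$intercept[1], x$intercept[2], x$intercept[3],
              x$slope[1], x$slope[2], x$slope[3]))
  if (!x$converged) cat("warning: recalibration fit did not converge\n")
  invisible(x)
}

#' @export
plot.calibration_result <- function(x, ...) {
  plot(x$curve$predicted, x$curve$observed, type = "l",
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "predicted risk", ylab = "observed proportion", ...)
  graphics::abline(0, 1, lty = 2, col = "red")
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)` per model over a grid
#' of risk thresholds, with the treat-all reference
#' `pi - (1-pi) * t/(1-t)` (prevalence `pi`) and the treat-none reference 0.
#'
#' @param risks_by_model named list of risk vectors (one per model).
#' @param labels logical/0-1 outcomes.
#' @param thresholds threshold grid, default 1% to 50% in 1% steps.
#' @return object of class `decision_curve`: data.frame with columns
#'   `threshold`, `model`, `net_benefit` (models plus `treat_all` and
#'   `treat_none`).
#' @export
decision_curve <- function(risks_by_model, labels,
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie in (0, 1)")
  if (!is.list(risks_by_model)) risks_by_model <- list(model = risks_by_model)
  labels <- as.logical(labels)
  n <- length(labels)
  prev <- mean(labels)
  rows <- lapply(names(risks_by_model), function(nm) {
    r <- risks_by_model[[nm]]
    nb <- vapply(thresholds, function(t) {
      pred <- r >= t
      sum(pred & labels) / n - sum(pred & !labels) / n * t / (1 - t)
    }, numeric(1))
    data.frame(threshold = thresholds, model = nm, net_benefit = nb)
  })
  out <- rbind(
    do.call(rbind, rows),
    data.frame(threshold = thresholds, model = "treat_all",
               net_benefit = prev - (1 - prev) * thresholds / (1 - thresholds)),
    data.frame(threshold = thresholds, model = "treat_none", net_benefit = 0))
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' @export
plot.decision_curve <- function(x, ...) {
  models <- unique(x$model)
  cols <- seq_along(models)
  plot(NULL, xlim = range(x$threshold),
       ylim = range(x$net_benefit, na.rm = TRUE),
       xlab = "threshold probability", ylab = "net benefit", ...)
  for (i in seq_along(models)) {
    sub <- x[x$model == models[i], ]
    graphics::lines(sub$threshold, sub$net_benefit, col = cols[i],
                    lty = if (models[i] %in% c("treat_all", "treat_none")) 2 else 1)
  }
  graphics::legend("topright", legend = models, col = cols,
                   lty = ifelse(models %in% c("treat_all", "treat_none"), 2, 1),
                   cex = 0.8)
  invisible(x)
}

#' SHAP-based overfitting diagnostic
#'
#' Computes exact TreeSHAP attributions (via the booster's per-feature
#' prediction contributions) on the training and validation matrices, the
#' mean absolute attribution of each feature on each split, and the
#' Overfit_Score = train minus validation. A feature whose attributions do
#' real work on the training split but collapse on validation (a memorized
#' training artifact) shows a large positive score. Attributions satisfy
#' local additivity: per case they sum to the prediction margin.
#'
#' @param model a tree-based `risk_model`.
#' @param train_x,val_x raw feature matrices for the two splits.
#' @return object of class `overfit_table`: data.frame with columns
#'   `feature`, `shap_train`, `shap_val`, `overfit_score`, sorted by
#'   descending score; max additivity residual in attribute
#'   `"additivity_residual"`.
#' @export
shap_overfit_table <- function(model, train_x, val_x) {
  if (!model$algorithm %in% c("gradient_boosted_trees", "random_forest"))
    stopf("SHAP attributions require a tree-based model")
  mean_abs_shap <- function(x) {
    xs <- apply_scaler(model$scaler, x)
    dm <- xgboost::xgb.DMatrix(xs, nthread = 1)
    contrib <- predict(model$fit, dm, predcontrib = TRUE)
    margin <- predict(model$fit, dm, outputmargin = TRUE)
    resid <- max(abs(rowSums(contrib) - margin))
    cols <- setdiff(colnames(contrib), c("BIAS", "(Intercept)"))
    list(m = colMeans(abs(contrib[, cols, drop = FALSE])), resid = resid)
  }
  tr <- mean_abs_shap(train_x)
  va <- mean_abs_shap(val_x)
  out <- data.frame(feature = names(tr$m),
                    shap_train = unname(tr$m),
                    shap_val = unname(va$m[names(tr$m)]),
                    stringsAsFactors = FALSE)
  out$overfit_score <- out$shap_train - out$shap_val
  out <- out[order(-out$overfit_score), ]
  rownames(out) <- NULL
  attr(out, "additivity_residual") <- max(tr$resid, va$resid)
  class(out) <- c("overfit_table", "data.frame")
  out
}

#' Manufacturer PCA diagnostic
#'
#' PCA of the (Z-scaled) selected features in the training set, with a
#' per-manufacturer overlap summary: if per-ROI normalization removed the
#' scanner gain/offset, the tag clusters overlap (small ratio of
#' between-tag centroid distance to within-tag spread in the first two
#' components).
#'
#' @param x feature matrix (training set, selected features).
#' @param tags manufacturer tag per case.
#' @return list with `scores` (first two PCs), `variance_explained`,
#'   `dispersion` (per-tag centroid and spread) and `overlap_ratio`.
#' @export
manufacturer_pca <- function(x, tags) {
  tags <- as.character(tags)
  if (length(unique(tags)) < 2)
    warning("single manufacturer tag: clusters overlap trivially")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1:2, drop = FALSE]
  disp <- do.call(rbind, lapply(unique(tags), function(tg) {
    s <- scores[tags == tg, , drop = FALSE]
    ctr <- colMeans(s)
    data.frame(tag = tg, n = nrow(s), pc1 = ctr[1], pc2 = ctr[2],
               spread = sqrt(mean(rowSums(sweep(s, 2, ctr)^2))))
  }))
  centroids <- as.matrix(disp[, c("pc1", "pc2")])
  between <- if (nrow(centroids) > 1) mean(dist(centroids)) else 0
  list(scores = scores,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2),
       dispersion = disp,
       overlap_ratio = between / mean(disp$spread))
}

#' Full evaluation report for a vector of predicted risks
#'
#' Assembles discrimination (bootstrap AUC), classification metrics at the
#' clinical 10% cutoff and the Youden-optimal cutoff, calibration, and the
#' decision curve into one report.
#'
#' @param risks predicted risks.
#' @param labels logical/0-1 outcomes.
#' @param cutoffs fixed cutoffs to report (default 0.10).
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param seed RNG seed (bootstrap).
#' @param dca_thresholds decision-curve threshold grid.
#' @return object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(risks, labels, cutoffs = 0.10,
                                 n_boot = 2000, seed = 1,
                                 dca_thresholds = seq(0.01, 0.50, by = 0.01)) {
  yc <- youden_cutoff(risks, labels)
  at_cut <- lapply(cutoffs, function(ct) metrics_at_cutoff(risks, labels, ct))
  names(at_cut) <- sprintf("cutoff_%g", cutoffs)
  at_cut$youden <- metrics_at_cutoff(risks, labels, yc$cutoff)
  structure(list(
    auc = auc_ci(risks, labels, n_boot = n_boot, seed = seed),
    youden = yc,
    metrics = at_cut,
    calibration = calibration(risks, labels),
    decision_curve = decision_curve(list(model = risks), labels,
                                    thresholds = dca_thresholds),
    n = length(labels),
    n_events = sum(as.logical(labels))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d (%d events)\n", x$n, x$n_events))
  print(x$auc)
  cat(sprintf("Youden-optimal cutoff %.2f (J = %.2f)\n", x$youden$cutoff, x$youden$j))
  for (m in x$metrics) print(m)
  print(x$calibration)
  invisible(x)
}
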