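# Discrimination, classification, calibration, decision curves, SHAP
# overfitting scores and the manufacturer PCA check.

test_that("AUC follows the pairwise concordance identity", {
  risks <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  expect_equal(auc_estimate(risks, labels), 0.75)          # 3 of 4 pairs
  expect_equal(auc_estimate(risks, 1 - labels), 0.25)      # label flip
  expect_equal(auc_estimate(c(0.1, 0.2, 0.8, 0.9), labels), 1)
  expect_error(auc_estimate(risks, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals U / (n1 n0) on random data", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(10:80, 1)
    r <- round(runif(n), sample(1:3, 1))  # force ties sometimes
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    u <- unname(suppressWarnings(
      wilcox.test(r[y == 1], r[y == 0])$statistic))
    expect_equal(auc_estimate(r, y), u / (sum(y) * sum(1 - y)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap AUC CI brackets the estimate and matches pROC's point AUC", {
  set.seed(21)
  r <- runif(200)
  y <- rbinom(200, 1, plogis(4 * (r - 0.5)))
  a <- auc_ci(r, y, n_boot = 500, seed = 1)
  expect_lte(a$ci[1], a$auc)
  expect_gte(a$ci[2], a$auc)
  expect_equal(a$auc,
               as.numeric(pROC::auc(pROC::roc(y, r, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("DeLong comparison: identity, symmetry and jackknife variance", {
  set.seed(22)
  r <- runif(30); y <- rep(c(0, 1), 15)
  same <- delong_compare(r, r, y)
  expect_equal(same$p_value, 1)
  r2 <- runif(30)
  ab <- delong_compare(r, r2, y)
  ba <- delong_compare(r2, r, y)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  expect_error(delong_compare(r, r2[-1], y), "paired")

  # n = 8: variance equals the leave-one-out jackknife oracle
  set.seed(23)
  for (rep in 1:10) {
    ra <- runif(8); rb <- runif(8)
    yy <- c(0, 0, 0, 0, 1, 1, 1, 1)
    got <- delong_compare(ra, rb, yy)
    expect_equal(got$se^2, oracle_delong_var(ra, rb, yy), tolerance = 1e-10)
  }
})

test_that("classification metrics come from the confusion matrix", {
  m <- metrics_at_cutoff(c(0.2, 0.05, 0.9, 0.6), c(0, 0, 1, 1), 0.10)
  expect_equal(m$sensitivity[1], 1)
  expect_equal(m$specificity[1], 0.5)
  expect_equal(m$ppv[1], 2 / 3)
  expect_equal(m$npv[1], 1)
  expect_equal(m$lr_pos[1], 2)
  expect_equal(m$lr_neg[1], 0)
  # all risks below the cutoff
  m0 <- metrics_at_cutoff(c(0.01, 0.02, 0.03, 0.04), c(0, 0, 1, 1), 0.5)
  expect_equal(m0$sensitivity[1], 0)
  expect_equal(m0$specificity[1], 1)
  expect_error(metrics_at_cutoff(c(0.1, 0.9), c(0, 1), 1.2), "cutoff")
  # normal-approximation CI arithmetic
  set.seed(24)
  r <- runif(200); y <- rbinom(200, 1, r)
  mm <- metrics_at_cutoff(r, y, 0.3)
  p <- mm$sensitivity[1]; n1 <- sum(y)
  expect_equal(mm$sensitivity[2], p - 1.96 * sqrt(p * (1 - p) / n1),
               tolerance = 1e-3)
})

test_that("the Youden scan finds the documented optimum with low-tie preference", {
  risks <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  yc <- youden_cutoff(risks, labels)
  expect_equal(yc$j, 0.5)
  expect_equal(yc$cutoff, 0.35)  # 0.8 ties at J = 0.5; lowest wins
  expect_equal(youden_cutoff(c(0.1, 0.2, 0.9, 0.95), labels)$j, 1)
  # sweep consistency: J from metrics_at_cutoff at the chosen cutoff agrees
  m <- metrics_at_cutoff(risks, labels, yc$cutoff)
  expect_equal(m$sensitivity[1] + m$specificity[1] - 1, yc$j)
})

test_that("calibration recovers (0, 1) on self-consistent risks", {
  set.seed(25)
  lp <- rnorm(1e4, 0, 1.5)
  r <- plogis(lp)
  y <- rbinom(1e4, 1, r)
  cal <- calibration(r, y)
  expect_lt(abs(cal$intercept[1]), 0.1)
  expect_lt(abs(cal$slope[1] - 1), 0.05)
  expect_true(cal$converged)
  # smoothed curve tracks the diagonal
  ok <- !is.na(cal$curve$observed)
  expect_lt(median(abs(cal$curve$observed[ok] - cal$curve$predicted[ok])), 0.1)
})

test_that("calibration flags systematic underestimation and distortion", {
  set.seed(26)
  lp <- rnorm(5000, 0, 1.5)
  y <- rbinom(5000, 1, plogis(lp))
  r_halved <- plogis(lp - log(2))        # odds uniformly halved
  expect_gt(calibration(r_halved, y)$intercept[1], 0)
  # injected slope: y drawn under b * logit(r)
  b <- 0.6
  y_b <- rbinom(5000, 1, plogis(b * lp))
  expect_lt(abs(calibration(plogis(lp), y_b)$slope[1] - b), 0.1)
  expect_error(calibration(rep(0.4, 50), rbinom(50, 1, 0.4)), "constant")
})

test_that("net benefit matches its closed forms", {
  set.seed(27)
  y <- rbinom(300, 1, 0.4)
  r <- runif(300)
  dc <- decision_curve(list(m = r), y)
  ta <- dc[dc$model == "treat_all", ]
  prev <- mean(y)
  expect_equal(ta$net_benefit,
               prev - (1 - prev) * ta$threshold / (1 - ta$threshold),
               tolerance = 1e-12)
  expect_true(all(dc[dc$model == "treat_none", "net_benefit"] == 0))
  # perfect classifier: NB = prevalence at every threshold
  perfect <- ifelse(y == 1, 0.99, 0.01)
  dcp <- decision_curve(list(p = perfect), y,
                        thresholds = seq(0.05, 0.5, by = 0.05))
  expect_equal(dcp[dcp$model == "p", "net_benefit"],
               rep(prev, 10), tolerance = 1e-12)
  expect_error(decision_curve(list(m = r), y, thresholds = c(0, 0.5)),
               "thresholds")
})

test_that("SHAP overfit scores vanish when train and validation coincide", {
  set.seed(28)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = y + rnorm(n, sd = 0.5), f2 = rnorm(n))
  m <- risk_model(x, y, "gradient_boosted_trees", n_search = 2, seed = 29)
  ot <- shap_overfit_table(m, x, x)
  expect_true(all(abs(ot$overfit_score) < 1e-12))
  expect_lt(attr(ot, "additivity_residual"), 1e-5)
  toy_lr <- risk_model(x, y, "penalized_logistic", n_search = 2, seed = 29)
  expect_error(shap_overfit_table(toy_lr, x, x), "tree-based")
})

test_that("manufacturer PCA shows overlap when the scanner effect is removed", {
  # cohort with manufacturer gain/offset; per-ROI normalization removes it
  coh <- generate_cohort(cohort_spec(90, seed = 33, image_size = 64,
                                     n_manufacturers = 3))
  fm <- extract_feature_matrix(coh)
  tags <- cohort_clinical(coh)$manufacturer
  res <- manufacturer_pca(fm, tags)
  expect_lt(res$overlap_ratio, 0.5)
  expect_true(all(diff(res$variance_explained) <= 1e-12))
  # random tags on exchangeable rows: overlap as well
  set.seed(34)
  res2 <- manufacturer_pca(matrix(rnorm(600), 100, 6),
                           sample(c("a", "b"), 100, TRUE))
  expect_lt(res2$overlap_ratio, 0.5)
  expect_warning(manufacturer_pca(matrix(rnorm(100), 50, 2), rep("a", 50)),
                 "single")
})

test_that("the evaluation report assembles every battery component", {
  set.seed(35)
  r <- runif(150)
  y <- rbinom(150, 1, plogis(3 * (r - 0.5)))
  ev <- evaluate_predictions(r, y, n_boot = 200)
  expect_s3_class(ev, "evaluation_report")
  expect_named(ev$metrics, c("cutoff_0.1", "youden"))
  expect_s3_class(ev$auc, "auc_ci")
  expect_s3_class(ev$calibration, "calibration_result")
  expect_s3_class(ev$decision_curve, "decision_curve")
})
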