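# Stratified splitting, tuned risk models, the missing-CA125 contract,
# EPV arithmetic and gain importance.

make_toy <- function(n = 80, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = y * sep + rnorm(n),
             f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("the stratified split follows the round-half-up allocation", {
  outcomes <- c(rep("benign", 6), rep("stage_III_IV", 4))
  sp <- stratified_split(outcomes, seed = 5)
  expect_equal(sum(outcomes[sp$validation] == "benign"), 2)       # round(1.8)
  expect_equal(sum(outcomes[sp$validation] == "stage_III_IV"), 1) # round(1.2)
  # partition
  expect_setequal(c(sp$train, sp$validation), seq_along(outcomes))
  expect_length(intersect(sp$train, sp$validation), 0)
  # same sizes, different membership across seeds
  sp2 <- stratified_split(outcomes, seed = 6)
  expect_equal(length(sp2$validation), length(sp$validation))
  expect_false(identical(sp, sp2))
  expect_error(stratified_split(c("benign", "borderline")), "fewer than 2")
  expect_error(stratified_split(outcomes, train_fraction = 1), "fraction")
})

test_that("every algorithm reaches CV AUC 1 on a separable toy set", {
  toy <- make_toy(n = 60, sep = 8, seed = 2)
  for (alg in c("gradient_boosted_trees", "random_forest",
                "penalized_logistic", "svm")) {
    m <- risk_model(toy$x, toy$y, alg, n_search = 3, seed = 3)
    expect_gte(m$cv_auc, 0.999)
    p <- predict(m, toy$x)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("permuted labels give chance-level CV AUC", {
  toy <- make_toy(n = 120, sep = 3, seed = 4)
  y_perm <- sample(toy$y)
  m <- risk_model(toy$x, y_perm, "gradient_boosted_trees",
                  n_search = 3, seed = 5)
  expect_lt(abs(m$cv_auc - 0.5), 0.15)
})

test_that("fitting is deterministic given the seed", {
  toy <- make_toy(seed = 6)
  m1 <- risk_model(toy$x, toy$y, "gradient_boosted_trees", n_search = 6, seed = 7)
  m2 <- risk_model(toy$x, toy$y, "gradient_boosted_trees", n_search = 6, seed = 7)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_equal(m1$cv_results, m2$cv_results)
  expect_equal(predict(m1, toy$x), predict(m2, toy$x))
})

test_that("prediction is a pure function with risks in range", {
  toy <- make_toy(seed = 8)
  m <- risk_model(toy$x, toy$y, "random_forest", n_search = 3, seed = 9)
  p1 <- predict(m, toy$x)
  p2 <- predict(m, toy$x[c(1, 1, 2), ])
  expect_equal(unname(p2[1]), unname(p2[2]))
  expect_equal(unname(p2[1]), unname(p1[1]))
  set.seed(10)
  grid <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  pg <- predict(m, grid)
  expect_true(all(pg >= 0 & pg <= 1))
  expect_error(predict(m, matrix(0, 2, 2, dimnames = list(NULL, c("f1", "zz")))),
               "missing feature")
})

test_that("missing CA125 is routed by tree models and refused by the others", {
  set.seed(11)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = y * 2 + rnorm(n), ca125 = exp(rnorm(n, 3 + y)))
  x[sample(n, 20), "ca125"] <- NA
  for (alg in c("gradient_boosted_trees", "random_forest")) {
    m <- risk_model(x, y, alg, n_search = 2, seed = 12)
    p <- predict(m, x)
    expect_true(all(is.finite(p)))
  }
  expect_error(risk_model(x, y, "penalized_logistic", n_search = 2, seed = 12),
               "missing")
  expect_error(risk_model(x, y, "svm", n_search = 2, seed = 12), "missing")
  # and at prediction time for a clean-trained non-tree model
  x_clean <- x[!is.na(x[, "ca125"]), ]
  y_clean <- y[!is.na(x[, "ca125"])]
  m_lr <- risk_model(x_clean, y_clean, "penalized_logistic", n_search = 2, seed = 13)
  x_na <- x_clean
  x_na[1, "ca125"] <- NA
  expect_error(predict(m_lr, x_na), "missing")
})

test_that("saved models reload with identical predictions", {
  toy <- make_toy(seed = 20)
  for (alg in c("gradient_boosted_trees", "penalized_logistic")) {
    m <- risk_model(toy$x, toy$y, alg, n_search = 2, seed = 21)
    path <- withr::local_tempfile(fileext = ".rds")
    save_risk_model(m, path)
    m2 <- load_risk_model(path)
    expect_equal(predict(m2, toy$x), predict(m, toy$x))
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    expect_identical(meta$algorithm, alg)
    expect_identical(meta$feature_set, m$feature_set)
  }
})

test_that("EPV arithmetic and flagging are exact", {
  expect_equal(events_per_variable(254, 16)$epv, 15.88)
  expect_false(events_per_variable(254, 16)$flagged)
  e2 <- events_per_variable(100, 10)
  expect_equal(e2$epv, 10)
  expect_false(e2$flagged)
  e3 <- events_per_variable(9, 1)
  expect_equal(e3$epv, 9)
  expect_true(e3$flagged)
  expect_error(events_per_variable(10, 0), "n_predictors")
})

test_that("gain importance is normalized and ranks signal above noise", {
  set.seed(14)
  n <- 150
  y <- rep(c(0, 1), each = n / 2)
  x1 <- cbind(strong = y * 3 + rnorm(n))
  m1 <- risk_model(x1, y, "gradient_boosted_trees", n_search = 2, seed = 15)
  expect_equal(unname(gain_importance(m1)), 1)

  x2 <- cbind(strong = y * 3 + rnorm(n), noise = rnorm(n))
  m2 <- risk_model(x2, y, "gradient_boosted_trees", n_search = 2, seed = 16)
  imp <- gain_importance(m2)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_gt(imp["strong"], imp["noise"])
  toy <- make_toy(seed = 17)
  m_lr <- risk_model(toy$x, toy$y, "penalized_logistic", n_search = 2, seed = 17)
  expect_error(gain_importance(m_lr), "tree-based")
})
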