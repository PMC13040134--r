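# Risk-model training: stratified 70:30 split, randomized hyperparameter
# search with stratified 5-fold cross-validation (selection criterion =
# mean CV AUC), final refit on the full training split. Four classifier
# families are supported; the two tree families are fit through xgboost
# (boosted and random-forest mode), which routes missing CA 125 values
# natively, so the clinical variant never imputes.

#' Stratified train/validation split
#'
#' Per-stratum random partition: each outcome stratum contributes
#' `round(validation_fraction * stratum size)` cases (round-half-up) to the
#' validation set. Deterministic given the seed.
#'
#' @param outcomes character vector of outcome labels (or a `us_cohort`).
#' @param train_fraction training share, default 0.70.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(outcomes, train_fraction = 0.70, seed = 1) {
  if (inherits(outcomes, "us_cohort")) outcomes <- cohort_outcomes(outcomes)
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  strata <- unique(outcomes)
  with_seed(seed, {
    val <- integer(0)
    for (s in strata) {
      idx <- which(outcomes == s)
      if (length(idx) < 2)
        stopf("stratum '%s' has fewer than 2 cases", s)
      n_val <- round_half_up((1 - train_fraction) * length(idx))
      val <- c(val, sample(idx, n_val))
    }
    list(train = sort(setdiff(seq_along(outcomes), val)),
         validation = sort(val))
  })
}

# hyperparameter search spaces (deliberately modest, documented in the
# methods vignette); one draw = one candidate configuration
sample_hyperparameters <- function(algorithm, n_search) {
  draws <- vector("list", n_search)
  for (i in seq_len(n_search)) {
    draws[[i]] <- switch(algorithm,
      gradient_boosted_trees = list(
        max_depth = sample(2:6, 1),
        eta = sample(c(0.01, 0.05, 0.1, 0.2, 0.3), 1),
        nrounds = sample(c(100, 200, 300, 400, 600), 1),
        subsample = sample(c(0.7, 0.85, 1), 1),
        colsample_bytree = sample(c(0.7, 0.85, 1), 1),
        min_child_weight = sample(c(1, 3, 5), 1)),
      random_forest = list(
        num_parallel_tree = sample(c(100, 200, 400), 1),
        max_depth = sample(c(4, 6, 8, 10), 1),
        subsample = sample(c(0.632, 0.8), 1),
        colsample_bynode = sample(c(0.33, 0.5, 0.8), 1)),
      penalized_logistic = list(
        alpha = sample(c(0, 0.25, 0.5, 0.75, 1), 1),
        lambda = 10^runif(1, -4, 0)),
      svm = {
        kern <- sample(c("linear", "radial"), 1)
        list(kernel = kern,
             cost = 10^runif(1, -2, 2),
             gamma = if (kern == "radial") 10^runif(1, -3, 0) else NA)
      },
      stopf("unknown algorithm '%s'", algorithm))
  }
  unique(draws)
}

xgb_dmat <- function(x, y = NULL) {
  if (is.null(y)) xgboost::xgb.DMatrix(x, nthread = 1)
  else xgboost::xgb.DMatrix(x, label = y, nthread = 1)
}

fit_algorithm <- function(algorithm, x, y, hp) {
  switch(algorithm,
    gradient_boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = hp$max_depth, eta = hp$eta,
                    subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    min_child_weight = hp$min_child_weight),
      data = xgb_dmat(x, y), nrounds = hp$nrounds, verbose = 0),
    random_forest = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1, eta = 1,
                    num_parallel_tree = hp$num_parallel_tree,
                    max_depth = hp$max_depth, subsample = hp$subsample,
                    colsample_bynode = hp$colsample_bynode),
      data = xgb_dmat(x, y), nrounds = 1, verbose = 0),
    penalized_logistic = glmnet::glmnet(
      x = x, y = y, family = "binomial", alpha = hp$alpha,
      lambda = c(hp$lambda * 10, hp$lambda)),
    svm = {
      args <- list(x = x, y = factor(y, levels = c(0, 1)),
                   kernel = hp$kernel, cost = hp$cost,
                   probability = TRUE, scale = FALSE)
      if (hp$kernel == "radial") args$gamma <- hp$gamma
      do.call(e1071::svm, args)
    })
}

predict_algorithm <- function(algorithm, fit, x, hp) {
  switch(algorithm,
    gradient_boosted_trees = predict(fit, xgb_dmat(x)),
    random_forest = predict(fit, xgb_dmat(x)),
    penalized_logistic = as.numeric(
      predict(fit, newx = x, s = hp$lambda, type = "response")),
    svm = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    })
}

#' Fit a tuned malignancy risk model
#'
#' Randomized hyperparameter search (`n_search` draws from a per-algorithm
#' grid) scored by mean AUC over a stratified `cv_folds`-fold
#' cross-validation of the training data, followed by a final refit of the
#' best configuration on the full training split. Feature scaling
#' statistics are estimated on the training data and frozen into the model.
#'
#' Missing values (e.g. serum CA 125) are tolerated only by the two tree
#' families, which route them natively; `penalized_logistic` and `svm`
#' refuse matrices containing `NA` -- there is no imputation anywhere.
#'
#' @param x numeric training matrix, cases x predictors (selected radiomics
#'   features, optionally plus `age` and `ca125` for the clinical variant).
#' @param y outcome, logical or 0/1 (`TRUE` = malignant).
#' @param algorithm one of `"gradient_boosted_trees"`, `"random_forest"`,
#'   `"penalized_logistic"`, `"svm"`.
#' @param cv_folds cross-validation folds (default 5).
#' @param n_search number of random hyperparameter draws (default 25).
#' @param seed integer seed controlling folds, search and fits.
#' @param model_id optional identifier carried into predictions.
#' @param hyperparameters optional named list fixing the configuration; the
#'   randomized search is skipped (the fixed configuration is still scored
#'   by cross-validation).
#' @return object of class `risk_model`: list with `algorithm`,
#'   `feature_set`, `hyperparameters`, `scaler`, `cv_auc` (mean CV AUC of
#'   the chosen configuration), `cv_results`, `fit` and `seed`.
#' @examples
#' x <- cbind(f1 = c(rnorm(20), rnorm(20, 3)), f2 = rnorm(40))
#' y <- rep(c(0, 1), each = 20)
#' m <- risk_model(x, y, "penalized_logistic", n_search = 4, seed = 1)
#' predict(m, x)[1:3]
#' @export
risk_model <- function(x, y,
                       algorithm = c("gradient_boosted_trees", "random_forest",
                                     "penalized_logistic", "svm"),
                       cv_folds = 5, n_search = 25, seed = 1,
                       model_id = NULL, hyperparameters = NULL) {
  algorithm <- match.arg(algorithm)
  y <- as.numeric(as.logical(y))
  if (min(table(y)) < cv_folds)
    stopf("risk_model: need >= %d cases per class for %d-fold CV", cv_folds, cv_folds)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  tree_based <- algorithm %in% c("gradient_boosted_trees", "random_forest")
  if (!tree_based && anyNA(x))
    stopf("%s cannot handle missing predictor values (e.g. missing CA 125); use a tree-based algorithm",
          algorithm)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  with_seed(seed, {
    folds <- make_stratified_folds(y, cv_folds)
    candidates <- if (is.null(hyperparameters))
      sample_hyperparameters(algorithm, n_search)
    else list(hyperparameters)
    cv_auc <- vapply(candidates, function(hp) {
      fold_auc <- vapply(seq_len(cv_folds), function(k) {
        tr <- folds != k
        fit <- fit_algorithm(algorithm, xs[tr, , drop = FALSE], y[tr], hp)
        p <- predict_algorithm(algorithm, fit, xs[!tr, , drop = FALSE], hp)
        auc_estimate(p, y[!tr])
      }, numeric(1))
      mean(fold_auc)
    }, numeric(1))
    best <- candidates[[which.max(cv_auc)]]
    fit <- fit_algorithm(algorithm, xs, y, best)
    structure(list(
      algorithm = algorithm,
      feature_set = colnames(x),
      hyperparameters = best,
      scaler = scaler,
      cv_auc = max(cv_auc),
      cv_results = data.frame(candidate = seq_along(cv_auc), cv_auc = cv_auc),
      fit = fit,
      seed = seed,
      model_id = model_id %||% algorithm,
      n_train = nrow(x)
    ), class = "risk_model")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict malignancy risk
#'
#' Applies the model's frozen training-set scaler and returns a probability
#' of malignancy in `[0, 1]` per case. The model is never mutated.
#'
#' @param object a `risk_model`.
#' @param newdata numeric matrix containing the model's feature set.
#' @param ... unused.
#' @return numeric vector of risks, named by `newdata` rownames.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  xs <- apply_scaler(object$scaler, newdata)
  tree_based <- object$algorithm %in% c("gradient_boosted_trees", "random_forest")
  if (!tree_based && anyNA(xs))
    stopf("%s cannot predict cases with missing values", object$algorithm)
  risk <- predict_algorithm(object$algorithm, object$fit, xs,
                            object$hyperparameters)
  risk <- pmin(pmax(risk, 0), 1)
  names(risk) <- rownames(newdata)
  risk
}

#' Risk predictions as a tidy table
#'
#' @param model a `risk_model`.
#' @param newdata feature matrix with case ids as rownames.
#' @return data.frame with columns `case_id`, `model_id`, `risk`.
#' @export
predict_risk <- function(model, newdata) {
  risk <- predict(model, newdata)
  data.frame(case_id = rownames(newdata) %||% as.character(seq_along(risk)),
             model_id = model$model_id, risk = as.numeric(risk),
             stringsAsFactors = FALSE)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s on %d features (n = %d), CV AUC %.3f\n",
              x$algorithm, length(x$feature_set), x$n_train, x$cv_auc))
  hp <- x$hyperparameters
  cat("hyperparameters:",
      paste(names(hp), vapply(hp, format, character(1)), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  print(object)
  cat(sprintf("randomized search: %d candidates, CV AUC range [%.3f, %.3f]\n",
              nrow(object$cv_results), min(object$cv_results$cv_auc),
              max(object$cv_results$cv_auc)))
  if (object$algorithm %in% c("gradient_boosted_trees", "random_forest")) {
    cat("gain importance (top 10):\n")
    print(round(head(gain_importance(object), 10), 4))
  }
  invisible(object)
}

#' @export
coef.risk_model <- function(object, ...) {
  if (object$algorithm != "penalized_logistic")
    stopf("coefficients are only defined for penalized_logistic models")
  drop(as.matrix(coef(object$fit, s = object$hyperparameters$lambda)))
}

#' @export
plot.risk_model <- function(x, top = 15, ...) {
  imp <- gain_importance(x)
  imp <- head(imp, top)
  graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                    xlab = "normalized gain importance",
                    main = x$model_id, cex.names = 0.7, ...)
  invisible(x)
}

#' Events-per-variable ratio
#'
#' Outcome events divided by the number of model predictors, the standard
#' sample-size adequacy heuristic; values below 10 are flagged.
#'
#' @param n_events number of outcome events (malignant cases).
#' @param n_predictors number of model predictors.
#' @return list with `epv` (rounded to 2 decimals, half-up) and `flagged`
#'   (`TRUE` when EPV < 10).
#' @examples
#' events_per_variable(254, 16)  # epv 15.88
#' @export
events_per_variable <- function(n_events, n_predictors) {
  if (n_predictors < 1) stopf("n_predictors must be >= 1")
  ratio <- n_events / n_predictors
  list(epv = round_half_up(ratio * 100) / 100, flagged = ratio < 10)
}

#' Save / load a fitted risk model
#'
#' The artifact is an RDS file holding the model list (algorithm id,
#' hyperparameters, frozen scaler, feature set, seed) with the xgboost
#' booster replaced by its raw serialized bytes, plus a human-readable
#' JSON sidecar (`<path>.json`) with everything except the binary payload.
#'
#' @param model a `risk_model`.
#' @param path output file (e.g. `model.rds`).
#' @return (invisibly) `path`.
#' @export
save_risk_model <- function(model, path) {
  obj <- unclass(model)
  if (model$algorithm %in% c("gradient_boosted_trees", "random_forest"))
    obj$fit <- list(xgb_raw = xgboost::xgb.save.raw(model$fit))
  saveRDS(obj, path)
  meta <- obj[c("algorithm", "feature_set", "hyperparameters", "cv_auc",
                "seed", "model_id", "n_train")]
  meta$scaler <- unclass(model$scaler)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_risk_model
#' @return `load_risk_model()` returns the restored `risk_model`.
#' @export
load_risk_model <- function(path) {
  obj <- readRDS(path)
  if (is.list(obj$fit) && !is.null(obj$fit$xgb_raw))
    obj$fit <- xgboost::xgb.load.raw(obj$fit$xgb_raw)
  structure(obj, class = "risk_model")
}

#' Gain-based feature importance of a tree model
#'
#' Per-feature mean split gain (the average improvement in the objective
#' when the feature is used to split), normalized to sum to 1, in
#' descending order. Features never used in a split get importance 0.
#'
#' @param model a tree-based `risk_model`.
#' @return named numeric vector over the model's feature set.
#' @export
gain_importance <- function(model) {
  if (!model$algorithm %in% c("gradient_boosted_trees", "random_forest"))
    stopf("gain importance is only defined for tree-based models")
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$fit))
  splits <- dump[dump$Feature != "Leaf", c("Feature", "Gain")]
  gain <- stats::setNames(rep(0, length(model$feature_set)), model$feature_set)
  agg <- tapply(splits$Gain, splits$Feature, sum)
  gain[names(agg)] <- agg
  gain <- gain / sum(gain)
  sort(gain, decreasing = TRUE)
}
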