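# End-to-end orchestration: generate/load -> despeckle+normalize+extract ->
# select -> train -> evaluate, with full provenance (every seed and
# parameter in the manifest, output files hashed so a rerun with the same
# config reproduces identical artifacts).

#' Pipeline run configuration
#'
#' Defaults follow the analysis parameters the pipeline implements:
#' Mann-Whitney screen with BH correction at alpha = 0.05, Pearson
#' redundancy threshold |r| = 0.6, stratified 70:30 split, randomized
#' 5-fold-CV tuning, evaluation at the 10% clinical cutoff plus each
#' model's Youden-optimal cutoff, 2000 bootstrap resamples, decision
#' curves over 1-50%.
#'
#' @param cohort a [cohort_spec()] to generate, or `NULL` when reading.
#' @param input_dir directory with an existing cohort (see [read_cohort()]);
#'   ignored when `cohort` is given.
#' @param n_bins,kernel feature-extraction parameters.
#' @param selection_method,alpha,r_threshold,k feature-selection cascade
#'   parameters (see [select_features()]).
#' @param train_fraction,split_seed stratified split parameters.
#' @param algorithms_radiomics classifier families tried for the
#'   radiomics-only model (best training-CV AUC wins).
#' @param algorithms_clinical families tried for the clinical-radiomics
#'   model; restricted to the tree families, which natively route missing
#'   CA 125.
#' @param n_search,cv_folds,model_seed tuning parameters.
#' @param cutoffs fixed risk cutoffs to report.
#' @param n_boot bootstrap resamples for AUC CIs.
#' @param dca_thresholds decision-curve grid.
#' @param include_adnex also run the ADNEX-style comparator (its ultrasound
#'   predictors are synthesized conditionally on outcome).
#' @param adnex_seed seed for the synthesized ADNEX predictors.
#' @param output_dir where to write artifacts; `NULL` = in-memory only.
#' @return object of class `run_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL,
                            n_bins = 32, kernel = 3,
                            selection_method = "mwu_bh_pearson",
                            alpha = 0.05, r_threshold = 0.6, k = 14,
                            train_fraction = 0.70, split_seed = 1,
                            algorithms_radiomics = c("gradient_boosted_trees",
                                                     "random_forest",
                                                     "penalized_logistic", "svm"),
                            algorithms_clinical = c("gradient_boosted_trees",
                                                    "random_forest"),
                            n_search = 25, cv_folds = 5, model_seed = 1,
                            cutoffs = 0.10, n_boot = 2000,
                            dca_thresholds = seq(0.01, 0.50, by = 0.01),
                            include_adnex = TRUE, adnex_seed = 1,
                            output_dir = NULL) {
  if (is.null(cohort) && is.null(input_dir))
    stopf("pipeline_config: give either a cohort spec or an input_dir")
  if (!is.null(input_dir) && is.null(cohort) && !dir.exists(input_dir))
    stopf("pipeline_config: input_dir does not exist: %s", input_dir)
  if (alpha <= 0 || alpha > 1 || r_threshold <= 0 || r_threshold > 1)
    stopf("pipeline_config: thresholds out of range")
  known <- c("gradient_boosted_trees", "random_forest",
             "penalized_logistic", "svm")
  if (!all(c(algorithms_radiomics, algorithms_clinical) %in% known))
    stopf("unknown algorithm(s) in config")
  cfg <- mget(setdiff(ls(environment()), "known"))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds any subset of [pipeline_config()]'s arguments; a nested
#' `cohort:` block is passed to [cohort_spec()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$cohort)) raw$cohort <- do.call(cohort_spec, raw$cohort)
  do.call(pipeline_config, raw)
}

stage_msg <- function(run_quiet, fmt, ...) {
  if (!run_quiet) message(sprintf(paste0("[radnex] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes every stage in order and (optionally) writes the feature
#' matrix, selection result, predictions, evaluation report, curve tables
#' and a manifest recording all seeds, versions, parameters and output
#' hashes. Rerunning with an identical config reproduces identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return object of class `radnex_run`: list with `cohort_summary`,
#'   `features`, `split`, `selection`, `models`, `predictions`,
#'   `evaluation`, `comparison`, `overfit`, `manufacturer_pca`, `epv`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  cohort <- if (!is.null(config$cohort)) {
    stage_msg(quiet, "generating synthetic cohort (n = %d, seed %d)",
              config$cohort$n_cases, config$cohort$seed)
    generate_cohort(config$cohort)
  } else {
    stage_msg(quiet, "reading cohort from %s", config$input_dir)
    read_cohort(config$input_dir)
  }
  outcomes <- cohort_outcomes(cohort)
  y <- as.numeric(is_malignant(outcomes))
  clinical <- cohort_clinical(cohort)

  stage_msg(quiet, "extracting %d features x %d cases",
            length(feature_registry()), length(cohort))
  feats <- extract_feature_matrix(cohort, n_bins = config$n_bins,
                                  kernel = config$kernel)

  split <- stratified_split(outcomes, train_fraction = config$train_fraction,
                            seed = config$split_seed)
  tr <- split$train; va <- split$validation
  stage_msg(quiet, "stratified split: %d train / %d validation", length(tr), length(va))

  sel <- select_features(feats[tr, , drop = FALSE], y[tr],
                         method = config$selection_method,
                         alpha = config$alpha, r_threshold = config$r_threshold,
                         k = config$k, seed = config$model_seed)
  stage_msg(quiet, "selection (%s): %d significant -> %d kept",
            sel$method, length(sel$significant), length(sel$kept))

  x_rad <- feats[, sel$kept, drop = FALSE]
  x_clin <- cbind(x_rad,
                  age = clinical$age,
                  ca125 = clinical$ca125)
  rownames(x_clin) <- rownames(feats)

  tune_all <- function(x, algorithms, variant) {
    fits <- lapply(algorithms, function(alg) {
      stage_msg(quiet, "tuning %s (%s)", alg, variant)
      risk_model(x[tr, , drop = FALSE], y[tr], algorithm = alg,
                 cv_folds = config$cv_folds, n_search = config$n_search,
                 seed = config$model_seed,
                 model_id = paste0(variant, "_", alg))
    })
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "cv_auc"))]]
    best$model_id <- variant
    list(best = best, fits = fits)
  }
  rad <- tune_all(x_rad, config$algorithms_radiomics, "radiomics_only")
  clin_fit <- tune_all(x_clin, config$algorithms_clinical, "clinical_radiomics")
  model_rad <- rad$best
  model_clin <- clin_fit$best

  risks <- list(
    radiomics_only = predict(model_rad, x_rad[va, , drop = FALSE]),
    clinical_radiomics = predict(model_clin, x_clin[va, , drop = FALSE]))

  adnex <- NULL
  if (isTRUE(config$include_adnex)) {
    stage_msg(quiet, "running ADNEX-style comparator")
    adnex_in <- generate_adnex_inputs(clinical, seed = config$adnex_seed)
    adnex <- adnex_risk_table(adnex_in)
    risks$adnex <- adnex$risk_malignant[va]
  }

  stage_msg(quiet, "evaluating on the validation set")
  evaluation <- lapply(risks, evaluate_predictions, labels = y[va],
                       cutoffs = config$cutoffs, n_boot = config$n_boot,
                       seed = config$model_seed,
                       dca_thresholds = config$dca_thresholds)
  comparison <- compare_models(risks, y[va], cutoff = config$cutoffs[1],
                               n_boot = config$n_boot, seed = config$model_seed)
  dca <- decision_curve(risks, y[va], thresholds = config$dca_thresholds)

  # the overfitting diagnostic needs exact tree attributions: use the
  # best tree-based radiomics fit (the chosen model itself when tree-based)
  tree_fits <- Filter(function(m)
    m$algorithm %in% c("gradient_boosted_trees", "random_forest"), rad$fits)
  overfit <- if (length(tree_fits) > 0) {
    best_tree <- tree_fits[[which.max(vapply(tree_fits, `[[`, numeric(1),
                                             "cv_auc"))]]
    shap_overfit_table(best_tree, x_rad[tr, , drop = FALSE],
                       x_rad[va, , drop = FALSE])
  }
  mpca <- manufacturer_pca(x_rad[tr, , drop = FALSE],
                           clinical$manufacturer[tr])
  epv <- events_per_variable(sum(y[va]), ncol(x_clin))

  preds <- do.call(rbind, lapply(names(risks), function(nm)
    data.frame(case_id = clinical$case_id[va], model_id = nm,
               risk = as.numeric(risks[[nm]]), stringsAsFactors = FALSE)))

  run <- structure(list(
    cohort_summary = list(
      n = length(cohort),
      by_stratum = as.list(table(factor(outcomes, levels = outcome_levels()))),
      pct_malignant = 100 * mean(y),
      pct_ca125_missing = 100 * mean(is.na(clinical$ca125))),
    features = feats, split = split, selection = sel,
    models = list(radiomics_only = model_rad, clinical_radiomics = model_clin),
    predictions = preds, risks = risks, labels = y[va],
    evaluation = evaluation, comparison = comparison, decision_curves = dca,
    overfit = overfit, manufacturer_pca = mpca, epv = epv,
    adnex = adnex,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "radnex_run")

  if (!is.null(config$output_dir)) {
    run$manifest <- write_run(run, config)
  }
  stage_msg(quiet, "done in %.1f s", run$elapsed_s)
  run
}

# serialize run artifacts and build the manifest (no timestamps: reruns
# with an identical config must hash identically)
write_run <- function(run, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$output_dir
  write.csv(data.frame(case_id = rownames(run$features), run$features,
                       check.names = FALSE),
            file.path(od, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_bins = config$n_bins, kernel = config$kernel,
         registry = feature_registry(),
         package_version = as.character(utils::packageVersion("radnex"))),
    file.path(od, "features_meta.json"), auto_unbox = TRUE, digits = NA)
  write_selection(run$selection, file.path(od, "selection.json"))
  write.csv(run$predictions, file.path(od, "predictions.csv"), row.names = FALSE)
  write.csv(run$decision_curves, file.path(od, "decision_curves.csv"),
            row.names = FALSE)
  write.csv(run$evaluation[[1]]$calibration$curve,
            file.path(od, "calibration_curve_radiomics_only.csv"),
            row.names = FALSE)
  write.csv(run$comparison$table, file.path(od, "comparison.csv"),
            row.names = FALSE)
  overfit_tab <- run$overfit %||%
    data.frame(feature = character(0), shap_train = numeric(0),
               shap_val = numeric(0), overfit_score = numeric(0))
  write.csv(overfit_tab, file.path(od, "overfit_scores.csv"), row.names = FALSE)
  report <- lapply(run$evaluation, function(ev) list(
    auc = ev$auc$auc, auc_ci = ev$auc$ci,
    youden_cutoff = ev$youden$cutoff, youden_j = ev$youden$j,
    calibration_intercept = unname(ev$calibration$intercept),
    calibration_slope = unname(ev$calibration$slope),
    metrics = lapply(ev$metrics, function(m)
      lapply(m[c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                 "lr_pos", "lr_neg")], unname))))
  report$epv <- run$epv
  report$cohort <- run$cohort_summary
  jsonlite::write_json(report, file.path(od, "evaluation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("features.csv", "features_meta.json", "selection.json",
             "predictions.csv", "decision_curves.csv",
             "calibration_curve_radiomics_only.csv", "comparison.csv",
             "overfit_scores.csv", "evaluation_report.json")
  cfg <- unclass(config)
  cfg$cohort <- if (!is.null(cfg$cohort)) unclass(cfg$cohort)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radnex")),
    config = cfg,
    seeds = list(cohort = if (!is.null(config$cohort)) config$cohort$seed,
                 split = config$split_seed, model = config$model_seed,
                 adnex = config$adnex_seed),
    selected_algorithms = list(
      radiomics_only = run$models$radiomics_only$algorithm,
      clinical_radiomics = run$models$clinical_radiomics$algorithm),
    file_hashes = as.list(tools::md5sum(file.path(od, files)))
  )
  names(manifest$file_hashes) <- files
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.radnex_run <- function(x, ...) {
  cat(sprintf("<radnex_run> n = %d (%.1f%% malignant), %d features kept, EPV %.2f\n",
              x$cohort_summary$n, x$cohort_summary$pct_malignant,
              length(x$selection$kept), x$epv$epv))
  for (nm in names(x$evaluation)) {
    ev <- x$evaluation[[nm]]
    cat(sprintf("  %-20s AUC %.3f (%.3f-%.3f)\n", nm, ev$auc$auc,
                ev$auc$ci[1], ev$auc$ci[2]))
  }
  invisible(x)
}

#' @export
summary.radnex_run <- function(object, ...) {
  print(object)
  cat("\nmodel comparison:\n")
  print(object$comparison)
  cat("\ntop overfit scores:\n")
  print(head(object$overfit, 5))
  invisible(object)
}
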