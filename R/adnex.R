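# ADNEX-style multinomial risk calculator, the clinical comparator for the
# radiomics models. The calculator is a multinomial logit over five
# outcome classes (benign is the reference) on transformed ultrasound and
# clinical predictors, with a with-CA125 and a without-CA125 coefficient
# variant. Coefficients are loaded from a human-readable JSON file; the
# bundled file is a clearly-labelled SYNTHETIC stand-in with the published
# model's structure and sign-correct values (see its "note" field), and
# the calculator is tested for its structural contracts (probability
# simplex, predictor monotonicity), not against published numbers.

.adnex_env <- new.env(parent = emptyenv())

#' Load an ADNEX-style coefficient set
#'
#' @param path JSON coefficient file; defaults to the synthetic stand-in
#'   bundled with the package.
#' @return list with `classes`, `transforms`, `with_ca125`,
#'   `without_ca125` coefficient tables.
#' @export
adnex_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.adnex_env$default)) return(.adnex_env$default)
    path <- system.file("extdata", "adnex_coefficients_synthetic.json",
                        package = "radnex")
  }
  coefs <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("classes", "transforms", "with_ca125", "without_ca125")
                %in% names(coefs)))
  if (is.null(.adnex_env$default) &&
      grepl("adnex_coefficients_synthetic", path))
    .adnex_env$default <- coefs
  coefs
}

validate_adnex_input <- function(input) {
  req <- c("age", "max_lesion_diameter", "proportion_solid",
           "more_than_10_locules", "n_papillary_projections",
           "acoustic_shadows", "ascites", "oncology_center")
  missing_f <- setdiff(req, names(input))
  if (length(missing_f) > 0)
    stopf("adnex_risk: missing predictor(s): %s", paste(missing_f, collapse = ", "))
  if (input$age <= 0) stopf("adnex_risk: age must be > 0")
  if (input$max_lesion_diameter <= 0)
    stopf("adnex_risk: max_lesion_diameter must be > 0 mm")
  if (input$proportion_solid < 0 || input$proportion_solid > 1)
    stopf("adnex_risk: proportion_solid must be in [0, 1]")
  if (!input$n_papillary_projections %in% 0:4)
    stopf("adnex_risk: n_papillary_projections must be on the 0-4 scale")
  invisible(TRUE)
}

#' Risk of malignancy from an ADNEX-style model
#'
#' Multinomial-logistic softmax over five outcome classes (benign,
#' borderline, Stage I, Stage II-IV, metastatic) on the transformed
#' predictors; `risk_malignant = 1 - p_benign`.
#'
#' @param input named list / one-row data.frame with `age` (years), `ca125`
#'   (U/mL, may be `NA`), `max_lesion_diameter` (mm), `proportion_solid`
#'   (fraction of the maximal diameter, in `[0, 1]`),
#'   `more_than_10_locules` (logical), `n_papillary_projections` (0-4),
#'   `acoustic_shadows` (logical), `ascites` (logical), `oncology_center`
#'   (logical).
#' @param use_ca125 use the with-CA125 coefficient variant; must be `FALSE`
#'   when `ca125` is missing.
#' @param coefficients a coefficient set from [adnex_coefficients()].
#' @return list of class `adnex_risks`: `p_benign`, `p_borderline`,
#'   `p_stage_I`, `p_stage_II_IV`, `p_metastatic` (summing to 1) and
#'   `risk_malignant`.
#' @export
adnex_risk <- function(input, use_ca125 = TRUE,
                       coefficients = adnex_coefficients()) {
  validate_adnex_input(input)
  if (use_ca125 && (is.null(input$ca125) || is.na(input$ca125)))
    stopf("adnex_risk: use_ca125 = TRUE but ca125 is missing")
  if (use_ca125 && input$ca125 <= 0) stopf("adnex_risk: ca125 must be > 0 U/mL")
  tab <- if (use_ca125) coefficients$with_ca125 else coefficients$without_ca125
  x <- c(age = input$age,
         ca125 = if (use_ca125) log(input$ca125) else NA_real_,
         max_lesion_diameter = log(input$max_lesion_diameter),
         proportion_solid = input$proportion_solid,
         more_than_10_locules = as.numeric(input$more_than_10_locules),
         n_papillary_projections = input$n_papillary_projections,
         acoustic_shadows = as.numeric(input$acoustic_shadows),
         ascites = as.numeric(input$ascites),
         oncology_center = as.numeric(input$oncology_center))
  z <- vapply(tab, function(cf) {
    preds <- setdiff(names(cf), "intercept")
    cf$intercept + sum(unlist(cf[preds]) * x[preds])
  }, numeric(1))
  ez <- exp(c(benign = 0, z))
  p <- ez / sum(ez)
  structure(list(
    p_benign = unname(p["benign"]),
    p_borderline = unname(p["borderline"]),
    p_stage_I = unname(p["stage_I"]),
    p_stage_II_IV = unname(p["stage_II_IV"]),
    p_metastatic = unname(p["metastatic"]),
    risk_malignant = unname(1 - p["benign"])
  ), class = "adnex_risks")
}

#' @export
print.adnex_risks <- function(x, ...) {
  cat(sprintf(
    "ADNEX-style risks: benign %.3f | borderline %.3f | stage I %.3f | stage II-IV %.3f | metastatic %.3f -> malignant %.3f\n",
    x$p_benign, x$p_borderline, x$p_stage_I, x$p_stage_II_IV, x$p_metastatic,
    x$risk_malignant))
  invisible(x)
}

#' ADNEX-style risks for a table of cases
#'
#' The with-CA125 variant is used whenever a case's CA 125 value is
#' available, the without-CA125 variant otherwise (mirroring how the
#' calculator is applied when the marker is partly missing).
#'
#' @param inputs data.frame with one row per case (columns as in
#'   [adnex_risk()]; optional `case_id`).
#' @param coefficients a coefficient set.
#' @return data.frame of per-case class probabilities and `risk_malignant`.
#' @export
adnex_risk_table <- function(inputs, coefficients = adnex_coefficients()) {
  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    inp <- as.list(inputs[i, ])
    use_ca <- !is.null(inp$ca125) && !is.na(inp$ca125)
    as.data.frame(unclass(adnex_risk(inp, use_ca125 = use_ca,
                                     coefficients = coefficients)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(inputs$case_id)) out <- cbind(case_id = inputs$case_id, out)
  out
}

#' Synthesize ADNEX ultrasound predictors for a cohort
#'
#' The image generator does not produce caliper measurements, so the
#' ultrasound descriptors the calculator needs (lesion diameter, solid
#' proportion, locularity, papillations, shadows, ascites) are sampled
#' conditionally on the outcome stratum, with strong, clinically plausible
#' effects (e.g. solid proportion and ascites increase with stage,
#' acoustic shadows are most common in benign masses).
#'
#' @param clinical a [cohort_clinical()] table (needs `case_id`, `age`,
#'   `ca125`, `outcome`).
#' @param seed RNG seed.
#' @return the clinical table with the ADNEX predictor columns appended
#'   (`oncology_center` is `TRUE` throughout: a referral-center cohort).
#' @export
generate_adnex_inputs <- function(clinical, seed = 1) {
  pars <- list( # per stratum: diameter meanlog/sdlog, solid beta a/b,
                # P(>10 locules), papillation probs 0:4, P(shadows), P(ascites)
    benign       = list(dm = log(55), ds = 0.50, sa = 1.2, sb = 8.0, loc = 0.10,
                        pap = c(0.82, 0.08, 0.05, 0.03, 0.02), sh = 0.30, asc = 0.03),
    borderline   = list(dm = log(70), ds = 0.50, sa = 2.0, sb = 4.0, loc = 0.20,
                        pap = c(0.30, 0.20, 0.20, 0.15, 0.15), sh = 0.12, asc = 0.05),
    stage_I_II   = list(dm = log(85), ds = 0.45, sa = 3.5, sb = 2.5, loc = 0.25,
                        pap = c(0.45, 0.20, 0.15, 0.10, 0.10), sh = 0.10, asc = 0.10),
    stage_III_IV = list(dm = log(95), ds = 0.45, sa = 5.0, sb = 1.8, loc = 0.20,
                        pap = c(0.50, 0.15, 0.15, 0.10, 0.10), sh = 0.06, asc = 0.50),
    metastasis   = list(dm = log(80), ds = 0.50, sa = 4.0, sb = 2.0, loc = 0.15,
                        pap = c(0.60, 0.15, 0.10, 0.08, 0.07), sh = 0.08, asc = 0.30))
  with_seed(seed, {
    n <- nrow(clinical)
    out <- clinical
    out$max_lesion_diameter <- NA_real_
    out$proportion_solid <- NA_real_
    out$more_than_10_locules <- NA
    out$n_papillary_projections <- NA_integer_
    out$acoustic_shadows <- NA
    out$ascites <- NA
    for (i in seq_len(n)) {
      p <- pars[[clinical$outcome[i]]]
      out$max_lesion_diameter[i] <- rlnorm(1, p$dm, p$ds)
      out$proportion_solid[i] <- stats::rbeta(1, p$sa, p$sb)
      out$more_than_10_locules[i] <- runif(1) < p$loc
      out$n_papillary_projections[i] <- sample(0:4, 1, prob = p$pap)
      out$acoustic_shadows[i] <- runif(1) < p$sh
      out$ascites[i] <- runif(1) < p$asc
    }
    out$oncology_center <- TRUE
    out
  })
}

#' Compare risk models on a common case set
#'
#' Runs the evaluation battery on each risk vector (AUC with bootstrap CI;
#' accuracy, sensitivity, specificity, PPV, NPV, LR+ and LR- at the 10%
#' clinical cutoff and at each model's own Youden-optimal cutoff) and
#' performs pairwise DeLong AUC comparisons.
#'
#' @param risks_by_model named list of risk vectors on identical cases.
#' @param labels logical/0-1 outcomes.
#' @param cutoff shared clinical cutoff (default 0.10).
#' @param n_boot bootstrap resamples for the AUC CIs.
#' @param seed RNG seed.
#' @return object of class `model_comparison`: `table` (one row per model
#'   and cutoff), `delong` (pairwise p-value matrix), `reports`.
#' @export
compare_models <- function(risks_by_model, labels, cutoff = 0.10,
                           n_boot = 2000, seed = 1) {
  lens <- vapply(risks_by_model, length, integer(1))
  if (any(lens != length(labels)))
    stopf("compare_models: all models must score the identical case set")
  fmt_row <- function(model, which_cut, ct, met, auc_obj) {
    data.frame(model = model, cutoff_type = which_cut, cutoff = ct,
               auc = auc_obj$auc, auc_lo = auc_obj$ci[1], auc_hi = auc_obj$ci[2],
               accuracy = met$accuracy[1], sensitivity = met$sensitivity[1],
               specificity = met$specificity[1], ppv = met$ppv[1],
               npv = met$npv[1], lr_pos = met$lr_pos[1], lr_neg = met$lr_neg[1],
               stringsAsFactors = FALSE)
  }
  rows <- list(); reports <- list()
  for (nm in names(risks_by_model)) {
    r <- risks_by_model[[nm]]
    a <- auc_ci(r, labels, n_boot = n_boot, seed = seed)
    yc <- youden_cutoff(r, labels)
    rows[[paste0(nm, "_10")]] <-
      fmt_row(nm, "clinical_10pct", cutoff, metrics_at_cutoff(r, labels, cutoff), a)
    rows[[paste0(nm, "_youden")]] <-
      fmt_row(nm, "youden", yc$cutoff, metrics_at_cutoff(r, labels, yc$cutoff), a)
    reports[[nm]] <- list(auc = a, youden = yc)
  }
  nms <- names(risks_by_model)
  dl <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i != j)
      dl[i, j] <- delong_compare(risks_by_model[[i]], risks_by_model[[j]],
                                 labels)$p_value
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 delong = dl, reports = reports),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  cat("\npairwise DeLong p-values:\n")
  print(round(x$delong, 4))
  invisible(x)
}
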