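# On-disk cohort format: 8-bit grayscale PNG images and binary PNG masks,
# a clinical CSV with header case_id,age,ca125,manufacturer,outcome,
# subjective_malignant (empty cell = missing CA 125), and a JSON manifest
# recording the file layout and, when the cohort was synthesized, the
# generating spec.

#' Write a cohort to a directory
#'
#' @param cohort a `us_cohort` (or any list of `ultrasound_case` objects).
#' @param directory output directory; created if absent.
#' @return (invisibly) the path of the JSON manifest.
#' @seealso [read_cohort()] for the inverse; `read_cohort(write_cohort(x))`
#'   reproduces the cohort exactly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "images"), showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  for (cs in cohort) {
    png::writePNG(cs$image / 255,
                  file.path(directory, "images", paste0(cs$case_id, ".png")))
    png::writePNG(cs$mask + 0,   # writePNG needs a real-valued matrix
                  file.path(directory, "masks", paste0(cs$case_id, ".png")))
  }
  clin <- cohort_clinical(cohort)
  write.csv(clin, file.path(directory, "clinical.csv"), row.names = FALSE,
            na = "")
  manifest <- list(
    format = "radnex-cohort/1",
    n_cases = length(cohort),
    clinical_table = "clinical.csv",
    image_dir = "images",
    mask_dir = "masks",
    case_ids = vapply(cohort, `[[`, character(1), "case_id")
  )
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a directory
#'
#' Validates the clinical table (admissible outcome labels, positive ages,
#' positive CA 125 when present) and requires a mask for every image; an
#' empty CA 125 cell is parsed as missing.
#'
#' @param directory a directory produced by [write_cohort()] (or following
#'   the same layout).
#' @return a `us_cohort`.
#' @export
read_cohort <- function(directory) {
  clin_path <- file.path(directory, "clinical.csv")
  if (!file.exists(clin_path)) stopf("no clinical.csv in %s", directory)
  clin <- read.csv(clin_path, stringsAsFactors = FALSE,
                   colClasses = c(case_id = "character"))
  bad <- setdiff(unique(clin$outcome), outcome_levels())
  if (length(bad) > 0)
    stopf("unknown outcome label(s) in clinical table: %s; admissible labels are: %s",
          paste(bad, collapse = ", "), paste(outcome_levels(), collapse = ", "))
  cases <- vector("list", nrow(clin))
  for (i in seq_len(nrow(clin))) {
    id <- clin$case_id[i]
    img_path <- file.path(directory, "images", paste0(id, ".png"))
    msk_path <- file.path(directory, "masks", paste0(id, ".png"))
    if (!file.exists(img_path)) stopf("missing image for case_id %s", id)
    if (!file.exists(msk_path)) stopf("missing mask for case_id %s", id)
    img <- png::readPNG(img_path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(msk_path)
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    msk <- ifelse(msk > 0.5, 1L, 0L)
    dim(msk) <- dim(img)
    ca125 <- clin$ca125[i]
    if (!is.na(ca125) && ca125 <= 0) stopf("ca125 must be > 0 (case_id %s)", id)
    if (is.na(clin$age[i]) || clin$age[i] <= 0)
      stopf("age must be > 0 (case_id %s)", id)
    cases[[i]] <- structure(list(
      case_id = id,
      image = round(img * 255),
      mask = msk,
      age = clin$age[i],
      ca125 = ca125,
      manufacturer = as.character(clin$manufacturer[i]),
      outcome = clin$outcome[i],
      subjective_malignant = as.logical(clin$subjective_malignant[i])
    ), class = "ultrasound_case")
  }
  structure(cases, class = "us_cohort")
}
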