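# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

degenerate_roi_error <- function(case_id = NULL) {
  msg <- "DegenerateROI: masked pixels are constant; the ROI cannot be Z-score normalized"
  if (!is.null(case_id)) msg <- paste0(msg, " (case_id: ", case_id, ")")
  stop(errorCondition(msg, class = c("degenerate_roi", "error", "condition")))
}

is_binary_matrix <- function(m) is.matrix(m) && all(m %in% c(0, 1))

# stratified fold assignment: each class gets folds 1..k cycled over a shuffled order
make_stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
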