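#' Adaptive Wiener despeckling of a 2-D ultrasound image
#'
#' Local adaptive (Lee/Wiener) filter, the standard first step against
#' multiplicative speckle: for each pixel, the local mean `m` and local
#' variance `v` are computed over a square window, the noise variance `nu`
#' is estimated as the mean of all local variances, and the output is
#' `m + max(v - nu, 0) / max(v, nu) * (x - m)`. Flat regions collapse to
#' their local mean while high-variance structure is preserved. Image edges
#' are handled by symmetric (mirror) padding.
#'
#' @param image numeric matrix of pixel intensities.
#' @param kernel odd window size, default `3` (a 3x3 neighbourhood).
#' @param clip optional length-2 numeric range to clamp the output to
#'   (e.g. `c(0, 255)` for 8-bit input); `NULL` leaves values unclipped.
#' @return a numeric matrix of the same dimensions.
#' @examples
#' img <- matrix(rgamma(32 * 32, shape = 4, rate = 4 / 100), 32, 32)
#' out <- wiener_despeckle(img)
#' var(as.vector(out)) < var(as.vector(img))
#' @export
wiener_despeckle <- function(image, kernel = 3, clip = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("wiener_despeckle: `image` must be a numeric 2-D matrix")
  if (kernel < 3 || kernel %% 2 != 1)
    stopf("wiener_despeckle: `kernel` must be odd and >= 3, got %s", kernel)
  if (nrow(image) < kernel || ncol(image) < kernel)
    stopf("wiener_despeckle: image (%dx%d) smaller than kernel %d",
          nrow(image), ncol(image), kernel)
  h <- (kernel - 1L) / 2L
  padded <- pad_symmetric(image, h)
  m  <- box_mean(padded, kernel)
  m2 <- box_mean(padded^2, kernel)
  v  <- pmax(m2 - m^2, 0)
  nu <- mean(v)
  gain <- pmax(v - nu, 0) / pmax(v, nu)
  gain[v == 0 & nu == 0] <- 0          # constant image: pure local mean
  out <- m + gain * (image - m)
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  out
}

# mirror-pad a matrix by `h` pixels on every side
pad_symmetric <- function(m, h) {
  if (h == 0) return(m)
  ri <- c(h:1, seq_len(nrow(m)), nrow(m) - 0:(h - 1))
  ci <- c(h:1, seq_len(ncol(m)), ncol(m) - 0:(h - 1))
  m[ri, ci, drop = FALSE]
}

# moving-window box mean over a padded matrix via 2-D cumulative sums;
# returns a matrix of the original (unpadded) dimensions
box_mean <- function(padded, kernel) {
  cs <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  nr <- nrow(padded) - kernel + 1L
  nc <- ncol(padded) - kernel + 1L
  i1 <- seq_len(nr); i2 <- i1 + kernel - 1L
  j1 <- seq_len(nc); j2 <- j1 + kernel - 1L
  (cs[i2 + 1L, j2 + 1L, drop = FALSE] - cs[i1, j2 + 1L, drop = FALSE] -
     cs[i2 + 1L, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]) / kernel^2
}

#' Z-score normalization of a region of interest
#'
#' Standardizes the masked pixels of an image: the ROI mean is subtracted
#' from every in-mask pixel and the difference is divided by the ROI's
#' sample standard deviation (n-1 denominator). Pixels outside the mask are
#' excluded from every downstream computation. The result is invariant to
#' any affine transform `a*image + b` (a > 0) of the input intensities,
#' which is what removes global gain/offset differences between scanners.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same dimensions (1 = inside ROI).
#' @param case_id optional identifier carried into error messages and the
#'   returned object.
#' @return an object of class `normalized_roi`: a list with `zmat` (matrix of
#'   Z-scores, `NA` outside the mask), `mask`, `values` (in-mask Z-scores in
#'   column-major order), `coords` (their row/col indices), `raw_mean`,
#'   `raw_sd` and `source_case_id`.
#' @examples
#' img <- matrix(c(2, 4, 6, 9), 2, 2)
#' msk <- matrix(c(1, 1, 1, 0), 2, 2)
#' zscore_roi(img, msk)$values   # -1, 0, 1
#' @export
zscore_roi <- function(image, mask, case_id = NULL) {
  if (!is.matrix(image) || !all(dim(image) == dim(mask)))
    stopf("zscore_roi: image and mask must be matrices of identical dimensions")
  if (!is_binary_matrix(mask))
    stopf("zscore_roi: mask must be binary (0/1)")
  inside <- which(mask == 1)
  if (length(inside) == 0) stopf("zscore_roi: empty mask")
  vals <- image[inside]
  mu <- mean(vals)
  sdev <- sd(vals)                      # sample SD, n-1
  if (!is.finite(sdev) || sdev == 0) degenerate_roi_error(case_id)
  z <- (vals - mu) / sdev
  zmat <- matrix(NA_real_, nrow(image), ncol(image))
  zmat[inside] <- z
  structure(list(
    zmat = zmat,
    mask = mask,
    values = z,
    coords = arrayInd(inside, dim(image)),
    raw_mean = mu,
    raw_sd = sdev,
    source_case_id = case_id
  ), class = "normalized_roi")
}

#' @export
print.normalized_roi <- function(x, ...) {
  cat(sprintf("<normalized_roi> %d pixels, raw mean %.3f, raw sd %.3f\n",
              length(x$values), x$raw_mean, x$raw_sd))
  invisible(x)
}
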