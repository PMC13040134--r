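# Independent brute-force oracles used to verify the implementation.
# These deliberately re-derive each quantity from its definition with
# plain enumeration, not by sharing code with the package.

# --- texture-matrix oracles -------------------------------------------------
# labels: integer matrix, 0 = outside mask, 1..nlevels inside

# all in-mask distance-1 pixel pairs over the four 2-D directions,
# enumerated pixel by pixel and counted symmetrically
oracle_glcm <- function(labels, nlevels) {
  nr <- nrow(labels); nc <- ncol(labels)
  m <- matrix(0, nlevels, nlevels)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a <- labels[r, c]
    if (a == 0) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      b <- labels[r2, c2]
      if (b == 0) next
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  m
}

# maximal runs found by slicing every grid line per direction, masking
# gaps with NA and run-length-encoding each in-mask segment
oracle_glrlm <- function(labels, nlevels) {
  nr <- nrow(labels); nc <- ncol(labels)
  lab_na <- labels
  lab_na[lab_na == 0] <- NA
  lines <- list()
  for (r in seq_len(nr)) lines <- c(lines, list(lab_na[r, ]))          # 0 deg
  for (c in seq_len(nc)) lines <- c(lines, list(lab_na[, c]))          # 90 deg
  for (d in (-(nr - 1)):(nc - 1)) {                                    # 45 deg
    idx <- which(col(labels) - row(labels) == d)
    o <- order(row(labels)[idx], decreasing = TRUE)  # walk up-right
    lines <- c(lines, list(lab_na[idx[o]]))
  }
  for (d in 2:(nr + nc)) {                                             # 135 deg
    idx <- which(col(labels) + row(labels) == d)
    o <- order(row(labels)[idx], decreasing = TRUE)  # walk up-left
    lines <- c(lines, list(lab_na[idx[o]]))
  }
  maxlen <- max(nr, nc)
  m <- matrix(0, nlevels, maxlen)
  for (ln in lines) {
    r <- rle(ifelse(is.na(ln), -1, ln))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] > 0)
        m[r$values[k], r$lengths[k]] <- m[r$values[k], r$lengths[k]] + 1
    }
  }
  # trim trailing all-zero columns (same presentation as the implementation)
  last <- max(1, max(which(colSums(m) > 0), 1))
  m[, seq_len(last), drop = FALSE]
}

# 8-connected equal-label zones by breadth-first flood fill
oracle_glszm <- function(labels, nlevels) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (seen[r, c] || labels[r, c] == 0) next
    lev <- labels[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || labels[r2, c2] != lev) next
        seen[r2, c2] <- TRUE
        queue <- c(queue, list(c(r2, c2)))
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  maxsize <- max(vapply(zones, `[`, numeric(1), 2))
  m <- matrix(0, nlevels, maxsize)
  for (z in zones) m[z[1], z[2]] <- m[z[1], z[2]] + 1
  m
}

# --- adaptive Wiener filter oracle -----------------------------------------
# direct per-pixel windowed computation of the filter formula with
# symmetric padding
oracle_wiener <- function(img, kernel = 3) {
  h <- (kernel - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  loc_mean <- matrix(0, nr, nc); loc_var <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- numeric(0)
    for (dr in -h:h) for (dc in -h:h)
      vals <- c(vals, img[reflect(r + dr, nr), reflect(c + dc, nc)])
    loc_mean[r, c] <- mean(vals)
    loc_var[r, c] <- mean(vals^2) - mean(vals)^2
  }
  nu <- mean(loc_var)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- loc_var[r, c]
    g <- if (max(v, nu) == 0) 0 else max(v - nu, 0) / max(v, nu)
    out[r, c] <- loc_mean[r, c] + g * (img[r, c] - loc_mean[r, c])
  }
  out
}

# --- DeLong variance oracle -------------------------------------------------
# leave-one-out jackknife of the paired AUC difference, recomputing both
# AUCs from scratch on each reduced sample (within-class deletion)
oracle_delong_var <- function(ra, rb, labels) {
  raw_auc <- function(r, y) {
    pos <- r[y]; neg <- r[!y]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  labels <- as.logical(labels)
  d_full <- raw_auc(ra, labels) - raw_auc(rb, labels)
  jack_var <- function(cls) {
    idx <- which(labels == cls)
    d_i <- vapply(idx, function(i) {
      raw_auc(ra[-i], labels[-i]) - raw_auc(rb[-i], labels[-i])
    }, numeric(1))
    k <- length(idx)
    (k - 1) / k * sum((d_i - mean(d_i))^2)
  }
  jack_var(TRUE) + jack_var(FALSE)
}

# --- small synthetic fixtures ----------------------------------------------
# deterministic speckled test image with an elliptical mask
make_test_case <- function(seed = 1, size = 48, texture_amp = 0) {
  set.seed(seed)
  field <- matrix(100, size, size) +
    outer(seq_len(size), seq_len(size), function(r, c) 10 * sin(r / 9) * cos(c / 7))
  img <- field * matrix(rgamma(size^2, 4, 4), size, size)
  ctr <- size / 2
  mask <- outer(seq_len(size), seq_len(size), function(r, c)
    ((r - ctr) / (0.35 * size))^2 + ((c - ctr) / (0.28 * size))^2 <= 1)
  mode(mask) <- "integer"
  if (texture_amp > 0) {
    spots <- cbind(round(runif(4, ctr - 8, ctr + 8)), round(runif(4, ctr - 8, ctr + 8)))
    for (k in 1:4)
      img <- img + texture_amp * 200 *
        exp(-outer(seq_len(size), seq_len(size), function(r, c)
          (r - spots[k, 1])^2 + (c - spots[k, 2])^2) / 4)
  }
  list(case_id = sprintf("test_%d", seed), image = img, mask = mask)
}

# enumerate every 2-level n x n label grid as an integer matrix
all_two_level_grids <- function(n) {
  total <- 2^(n * n)
  lapply(seq_len(total) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n * n)]
    matrix(bits + 1L, n, n)
  })
}
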