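# Canny edge detection on an intensity matrix.
#
# Gaussian smoothing, Sobel gradients, non-maximum suppression along the
# quantized gradient direction, and dual-threshold hysteresis. Thresholds
# are fractions of the maximum gradient magnitude, matching the common
# normalized-threshold convention. None of the installed imaging packages
# exposes a Canny detector, so it is implemented here directly.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with edge replication.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  # rows (vertical pass)
  padr <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  v <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    v <- v + k[j] * padr[(j - 1L) + seq_len(nr), , drop = FALSE]
  }
  # columns (horizontal pass)
  padc <- v[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  h <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    h <- h + k[j] * padc[, (j - 1L) + seq_len(nc), drop = FALSE]
  }
  h
}

canny <- function(m, high = 0.3, low_ratio = 0.4, sigma = 1,
                  tie_break = NULL) {
  stopifnot(is.matrix(m))
  sm <- blur_gaussian(m, sigma)

  # Sobel gradients with replicated borders; gy increases downward.
  gx <- (shift_rep(sm, 0, -1) - shift_rep(sm, 0, 1)) * 2 +
    (shift_rep(sm, -1, -1) - shift_rep(sm, -1, 1)) +
    (shift_rep(sm, 1, -1) - shift_rep(sm, 1, 1))
  gy <- (shift_rep(sm, -1, 0) - shift_rep(sm, 1, 0)) * 2 +
    (shift_rep(sm, -1, -1) - shift_rep(sm, 1, -1)) +
    (shift_rep(sm, -1, 1) - shift_rep(sm, 1, 1))

  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax <= 0) {
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  mag <- mag / mmax

  # Quantize gradient direction into 4 bins (degrees mod 180).
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  bin <- integer(length(ang))
  bin[(ang < 22.5) | (ang >= 157.5)] <- 0L  # horizontal gradient -> E/W neighbors
  bin[ang >= 22.5 & ang < 67.5] <- 1L
  bin[ang >= 67.5 & ang < 112.5] <- 2L      # vertical gradient -> N/S neighbors
  bin[ang >= 112.5 & ang < 157.5] <- 3L
  bin <- matrix(bin, nrow(m), ncol(m))

  # Symmetric gradient profiles tie across the edge; a small bias toward
  # foreground pixels (when a binary source is given) thins such ties onto
  # the filament's own boundary row.
  magb <- mag
  if (!is.null(tie_break)) {
    magb <- mag * (1 + 1e-9 * tie_break)
  }

  nms <- matrix(FALSE, nrow(m), ncol(m))
  pairs <- list(
    `0` = list(c(0, -1), c(0, 1)),
    `1` = list(c(-1, 1), c(1, -1)),
    `2` = list(c(-1, 0), c(1, 0)),
    `3` = list(c(-1, -1), c(1, 1))
  )
  for (b in 0:3) {
    off <- pairs[[as.character(b)]]
    n1 <- shift_mat(magb, off[[1]][1], off[[1]][2])
    n2 <- shift_mat(magb, off[[2]][1], off[[2]][2])
    nms <- nms | (bin == b & magb >= n1 & magb >= n2 & mag > 0)
  }

  strong <- nms & (mag >= high)
  weak <- nms & (mag >= high * low_ratio)

  # Hysteresis: grow strong edges through connected weak pixels.
  repeat {
    grown <- strong |
      shift_mat(strong, -1, -1, FALSE) | shift_mat(strong, -1, 0, FALSE) |
      shift_mat(strong, -1, 1, FALSE) | shift_mat(strong, 0, -1, FALSE) |
      shift_mat(strong, 0, 1, FALSE) | shift_mat(strong, 1, -1, FALSE) |
      shift_mat(strong, 1, 0, FALSE) | shift_mat(strong, 1, 1, FALSE)
    grown <- grown & weak
    new_strong <- strong | grown
    if (identical(new_strong, strong)) break
    strong <- new_strong
  }
  strong
}
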