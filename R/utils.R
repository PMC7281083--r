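# Internal helpers shared across the pipeline.

# Classed conditions so callers can distinguish failure modes programmatically.
# All conditions inherit from "inktransition_error".
it_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "inktransition_error"),
                      call = call))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_count <- function(x) {
  is_scalar_number(x) && x >= 1 && abs(x - round(x)) < 1e-8
}

is_rgb <- function(x) {
  is.numeric(x) && length(x) == 3L && all(is.finite(x)) &&
    all(x >= 0) && all(x <= 1)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Rec. 601 luma weights; the convention of MATLAB's rgb2gray.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

# 90-10 span of a standard normal CDF profile, per unit sigma:
# qnorm(0.9) - qnorm(0.1) = 2 * qnorm(0.9) ~= 2.5631.
span_90_10_per_sigma <- function() 2 * stats::qnorm(0.9)

#' Centered moving average with symmetric end truncation
#'
#' Smooths a signal with a centered window of `window` samples. For odd
#' windows the kernel is a plain average over `window` points; for even
#' windows the symmetric `window + 1`-point kernel with half-weighted end
#' points is used (the standard centered moving average of even order), so
#' that smoothing never shifts the signal. Near the ends the window is
#' truncated symmetrically (equal reach on both sides), which reproduces a
#' linear signal exactly at every position.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (>= 1). `window = 1` returns `x`.
#' @return Numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  if (!is_count(window)) {
    it_stop("`window` must be a positive integer.", "inktransition_invalid_input")
  }
  window <- as.integer(window)
  if (window <= 1L || n <= 1L) return(x)

  if (window %% 2L == 1L) {
    h <- (window - 1L) %/% 2L
    kern <- rep(1 / window, window)
  } else {
    h <- window %/% 2L
    kern <- c(0.5, rep(1, window - 1L), 0.5) / window
  }

  out <- as.numeric(stats::filter(x, kern, sides = 2))
  # Symmetric truncation where the full kernel does not fit.
  for (i in seq_len(n)) {
    if (is.na(out[i])) {
      k <- min(i - 1L, n - i, h)
      out[i] <- mean(x[(i - k):(i + k)])
    }
  }
  out
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Shift with edge replication: out[r, c] = m[clamp(r - dr), clamp(c - dc)].
# Used for image gradients so the border behaves like a continued image and
# produces no spurious edges.
shift_rep <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  cs <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[rs, cs, drop = FALSE]
}
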