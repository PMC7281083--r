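#' Fit the through-origin diffusion growth law
#'
#' Fits D(t) = slope * t by least squares through the origin to measured
#' transition distances over elapsed time, modelling the apparent widening
#' of the transition caused by dye diffusion within the printed filament.
#' The closed-form slope is sum(t * d) / sum(t^2); the fit is delegated to
#' [stats::lm()] so a standard error is available for uncertainty
#' propagation. R-squared and the residual standard deviation are computed
#' about the through-origin model (total sum of squares about zero, the
#' no-intercept convention).
#'
#' An optional with-intercept fit is available for diagnostics; only
#' through-origin models can be used by [correct_transition()].
#'
#' @param times_s Elapsed times in seconds (>= 0, not all zero).
#' @param distances_mm Measured transition distances in mm, same length.
#' @param intercept Fit an intercept as a diagnostic (default `FALSE`).
#' @return An object of class `diffusion_model` with `slope_mm_per_s`,
#'   `slope_se`, `intercept_mm` (`NA` for through-origin fits),
#'   `n_points`, `r_squared`, `residual_sd_mm`, `negative_slope` flag.
#' @export
fit_diffusion_model <- function(times_s, distances_mm, intercept = FALSE) {
  if (length(times_s) != length(distances_mm)) {
    it_stop("`times_s` and `distances_mm` differ in length.",
            "inktransition_invalid_input")
  }
  n <- length(times_s)
  if (n < 1 || anyNA(times_s) || anyNA(distances_mm)) {
    it_stop("Need at least one complete (time, distance) pair.",
            "inktransition_invalid_input")
  }
  if (any(times_s < 0)) {
    it_stop("Elapsed times must be >= 0.", "inktransition_invalid_input")
  }
  if (all(times_s == 0)) {
    it_stop("All elapsed times are zero: the slope is unidentifiable.",
            "inktransition_degenerate_design")
  }

  d <- as.numeric(distances_mm)
  t <- as.numeric(times_s)
  # summary.lm warns on exact (zero-residual) data; the SE is then 0/NA and
  # the diagnostics below are computed directly, so the warning is suppressed.
  if (intercept) {
    fit <- stats::lm(d ~ t)
    slope <- unname(stats::coef(fit)["t"])
    b0 <- unname(stats::coef(fit)[1])
    se <- if (n > 2) {
      unname(suppressWarnings(summary(fit))$coefficients["t", "Std. Error"])
    } else NA_real_
  } else {
    fit <- stats::lm(d ~ t + 0)
    slope <- unname(stats::coef(fit)["t"])
    b0 <- NA_real_
    se <- if (n > 1) {
      unname(suppressWarnings(summary(fit))$coefficients["t", "Std. Error"])
    } else NA_real_
  }
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- if (intercept) sum((d - mean(d))^2) else sum(d^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  resid_sd <- if (n > 1) sqrt(ss_res / (n - 1)) else 0

  if (slope < 0) {
    warning("Fitted diffusion slope is negative; reported unclamped.",
            call. = FALSE)
  }
  structure(list(
    slope_mm_per_s = slope,
    slope_se = se,
    intercept_mm = b0,
    n_points = n,
    r_squared = r2,
    residual_sd_mm = resid_sd,
    negative_slope = slope < 0
  ), class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("<diffusion_model> D(t) = %.5f mm/s * t", x$slope_mm_per_s))
  if (!is.na(x$intercept_mm)) cat(sprintf(" + %.4f mm", x$intercept_mm))
  cat(sprintf("  (n = %d, R^2 = %.4f, residual sd = %.4f mm)\n",
              x$n_points, x$r_squared, x$residual_sd_mm))
  invisible(x)
}

#' Subtract the diffusion contribution from a measured transition
#'
#' Computes the deposition-time ("real") transition distance by subtracting
#' the diffusion model's prediction at the image's elapsed time from the
#' measured distance: corrected = distance_mm - slope * elapsed_s. Negative
#' corrected values are kept (flagged `negative_after_correction`), which
#' preserves unbiasedness when aggregating. When the model carries a slope
#' standard error the uncertainty is propagated as
#' sqrt(u_meas^2 + (elapsed_s * slope_se)^2).
#'
#' @param result A [measure_transition()] result.
#' @param model A through-origin [fit_diffusion_model()] result.
#' @param elapsed_s Elapsed time in seconds; defaults to the time recorded
#'   on the measurement. A missing elapsed time is an error — zero is never
#'   silently assumed.
#' @return The updated `transition_result` with `corrected_mm` set.
#' @export
correct_transition <- function(result, model, elapsed_s = result$elapsed_s) {
  if (!inherits(result, "transition_result")) {
    it_stop("`result` must be a transition_result.", "inktransition_invalid_input")
  }
  if (!inherits(model, "diffusion_model")) {
    it_stop("`model` must be a diffusion_model.", "inktransition_invalid_input")
  }
  if (!is.na(model$intercept_mm)) {
    it_stop("Correction requires a through-origin model (intercept fits are diagnostic only).",
            "inktransition_invalid_input")
  }
  if (is.null(elapsed_s) || length(elapsed_s) != 1 || is.na(elapsed_s)) {
    it_stop("Elapsed time since printing is unknown: refusing to correct.",
            "inktransition_correction_refused")
  }
  if (elapsed_s < 0) {
    it_stop("`elapsed_s` must be >= 0.", "inktransition_invalid_input")
  }

  result$corrected_mm <- result$distance_mm - model$slope_mm_per_s * elapsed_s
  result$elapsed_s <- as.numeric(elapsed_s)
  if (result$corrected_mm < 0) {
    result$flags <- union(result$flags, "negative_after_correction")
  }
  if (!is.na(model$slope_se)) {
    result$uncertainty_mm <- sqrt(result$uncertainty_mm^2 +
                                    (elapsed_s * model$slope_se)^2)
  }
  result
}
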