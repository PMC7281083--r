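#' Normalize the smoothed red signal to its own extremes
#'
#' Maps the smoothed red channel of a profile onto \[0, 1\] by its own
#' minimum and maximum, so that "90% of the maximum red value" refers to
#' the profile's own range. The normalization is invariant to affine
#' rescaling of the red channel.
#'
#' @param profile A [extract_profile()] result.
#' @return Numeric vector of normalized red values in \[0, 1\].
#' @export
normalize_red <- function(profile) {
  if (!inherits(profile, "color_profile")) {
    it_stop("`profile` must come from extract_profile().",
            "inktransition_invalid_input")
  }
  r <- profile$smoothed_rgb[, 1]
  if (length(r) < 2) {
    it_stop("Profile must have at least 2 positions.",
            "inktransition_invalid_input")
  }
  rng <- range(r)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    it_stop("Flat red profile: no transition to measure.",
            "inktransition_no_transition")
  }
  (r - rng[1]) / diff(rng)
}

#' Locate the 90% and 10% crossings of the normalized red signal
#'
#' Scanning in print direction, the transition end is the first position
#' where the normalized signal drops to `lo` or below, and the transition
#' start is the last position before it where the signal is at `hi` or
#' above (the outermost bracket; robust to small oscillations under noise).
#' For `b_to_a` profiles the signal is reversed first so the scan still
#' runs from the red side to the blue side. Crossings are refined to
#' sub-pixel positions by linear interpolation between the bracketing
#' samples unless `subpixel = FALSE`.
#'
#' @param r_norm Normalized red signal from [normalize_red()].
#' @param positions_px Axial positions matching `r_norm`.
#' @param hi,lo Crossing levels, `0 < lo < hi < 1` (defaults 0.9 and 0.1).
#' @param direction `"a_to_b"` or `"b_to_a"`.
#' @param subpixel Interpolate crossings between samples (default `TRUE`).
#' @return List with `start_px`, `end_px` (fractional positions along the
#'   axis, `start_px <= end_px`) and `clipped` (logical: a crossing sat on
#'   the profile boundary).
#' @export
find_crossings <- function(r_norm, positions_px, hi = 0.9, lo = 0.1,
                           direction = "a_to_b", subpixel = TRUE) {
  if (!(is_scalar_number(hi) && is_scalar_number(lo) && 0 < lo && lo < hi && hi < 1)) {
    it_stop("Need 0 < lo < hi < 1.", "inktransition_invalid_input")
  }
  if (length(r_norm) != length(positions_px)) {
    it_stop("`r_norm` and `positions_px` differ in length.",
            "inktransition_invalid_input")
  }
  r <- r_norm
  pos <- as.numeric(positions_px)
  if (direction == "b_to_a") {
    r <- rev(r)
    pos <- rev(pos)
  }

  idx_end <- which(r <= lo)
  if (length(idx_end) == 0) {
    it_stop(sprintf("Signal never falls to the lower bound %g: no transition end.", lo),
            "inktransition_no_transition")
  }
  idx_end <- idx_end[1]

  idx_start <- which(r[seq_len(idx_end - 1)] >= hi)
  if (idx_end == 1 || length(idx_start) == 0) {
    if (idx_end == 1) {
      it_stop(sprintf("Signal is already below %g at the profile start: no transition start.", lo),
              "inktransition_no_transition")
    }
    it_stop(sprintf("Signal never reaches the upper bound %g before falling to %g.", hi, lo),
            "inktransition_no_transition")
  }
  idx_start <- idx_start[length(idx_start)]

  clipped <- idx_start == 1 || idx_end == length(r)

  interp <- function(i, j, level) {
    # crossing of `level` between samples i (above) and j (below)
    if (!subpixel || r[i] == r[j]) return(pos[j])
    pos[i] + (r[i] - level) / (r[i] - r[j]) * (pos[j] - pos[i])
  }
  end_px <- interp(idx_end - 1L, idx_end, lo)
  start_px <- interp(idx_start, idx_start + 1L, hi)
  if (!subpixel) {
    end_px <- pos[idx_end]
    start_px <- pos[idx_start]
  }

  out <- sort(c(start_px, end_px))
  list(start_px = out[1], end_px = out[2], clipped = clipped)
}

#' Measure the 90-10 transition distance of a color profile
#'
#' Composes [normalize_red()] and [find_crossings()] and converts the
#' crossing span from pixels to millimetres. The reported uncertainty is
#' the larger of the stated measurement floor (0.02 mm) and one pixel at
#' the image scale. The diffusion-corrected distance is left unset until
#' [correct_transition()] is applied.
#'
#' @param profile A [extract_profile()] result with known `mm_per_px`.
#' @param hi,lo Crossing levels (defaults 0.9 and 0.1).
#' @param uncertainty_floor_mm Lower bound on the reported uncertainty, mm.
#' @param subpixel Sub-pixel crossing interpolation (default `TRUE`).
#' @return An object of class `transition_result` with `start_px`,
#'   `end_px`, `distance_px`, `distance_mm`, `corrected_mm` (`NA` until
#'   corrected), `uncertainty_mm`, `direction`, `flags`, and the source
#'   metadata (`mm_per_px`, `elapsed_s`, `condition`, `id`).
#' @export
measure_transition <- function(profile, hi = 0.9, lo = 0.1,
                               uncertainty_floor_mm = 0.02, subpixel = TRUE) {
  r_norm <- normalize_red(profile)
  flags <- character()
  direction <- profile$direction
  if (direction == "undetermined") {
    flags <- c(flags, "undetermined_direction")
    direction <- "a_to_b"
  }
  cr <- find_crossings(r_norm, profile$positions_px, hi = hi, lo = lo,
                       direction = direction, subpixel = subpixel)
  if (cr$clipped) flags <- c(flags, "clipped_at_boundary")

  distance_px <- cr$end_px - cr$start_px
  structure(list(
    start_px = cr$start_px,
    end_px = cr$end_px,
    distance_px = distance_px,
    distance_mm = distance_px * profile$mm_per_px,
    corrected_mm = NA_real_,
    uncertainty_mm = max(uncertainty_floor_mm, profile$mm_per_px),
    direction = profile$direction,
    flags = flags,
    mm_per_px = profile$mm_per_px,
    elapsed_s = profile$elapsed_s,
    condition = profile$condition,
    id = profile$id
  ), class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("<transition_result> '%s': %.2f px = %.3f +/- %.3f mm (%s)\n",
              x$id, x$distance_px, x$distance_mm, x$uncertainty_mm, x$direction))
  if (!is.na(x$corrected_mm)) {
    cat(sprintf("  diffusion-corrected: %.3f mm (elapsed %g s)\n",
                x$corrected_mm, x$elapsed_s))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate transition results
#'
#' Flattens a list of `transition_result` objects into a tibble with one
#' row per measurement, expanding the print-condition fields when present.
#'
#' @param results A `transition_result` or a list of them.
#' @return A tibble.
#' @export
transition_table <- function(results) {
  if (inherits(results, "transition_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    cond <- r$condition
    tibble::tibble(
      id = r$id,
      pressure_psi = if (is.null(cond)) NA_real_ else cond$pressure_psi,
      nozzle_id_um = if (is.null(cond)) NA_real_ else cond$nozzle_id_um,
      coated = if (is.null(cond)) NA else cond$coated,
      bioink_pair = if (is.null(cond)) NA_character_ else cond$bioink_pair,
      start_px = r$start_px,
      end_px = r$end_px,
      distance_px = r$distance_px,
      distance_mm = r$distance_mm,
      corrected_mm = r$corrected_mm,
      uncertainty_mm = r$uncertainty_mm,
      elapsed_s = r$elapsed_s,
      direction = r$direction,
      flags = paste(r$flags, collapse = ";")
    )
  })
  dplyr::bind_rows(rows)
}
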