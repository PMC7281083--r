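#' Binarize a filament photograph
#'
#' Converts the image to luminance (Rec. 601 weights) and thresholds it to
#' separate filament from background. The default threshold is Otsu's
#' method; a fixed threshold can be supplied instead. `TRUE` marks the
#' filament, taken as the minority class (the analyzed crop is expected to
#' contain more background than filament); when both classes are equally
#' large the darker class is used. The result is therefore unchanged when
#' foreground and background intensities are swapped.
#'
#' @param image A [raster_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Luminance threshold in \[0, 1\] when `method = "fixed"`.
#' @return An H x W logical matrix (`TRUE` = filament).
#' @export
to_binary <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  lum <- luminance(image)
  thr <- switch(method,
                otsu = EBImage::otsu(EBImage::Image(lum)),
                fixed = {
                  if (!is_scalar_number(threshold)) {
                    it_stop("`threshold` required for method = 'fixed'.",
                            "inktransition_invalid_input")
                  }
                  threshold
                })
  dark <- lum < thr
  n_dark <- sum(dark)
  n_total <- length(dark)
  if (n_dark == 0 || n_dark == n_total) {
    it_stop("Binarization produced a single class: no filament to separate.",
            "inktransition_no_filament")
  }
  if (n_dark <= n_total - n_dark) dark else !dark
}

luminance <- function(image) {
  px <- image$pixels
  LUMA_WEIGHTS[1] * px[, , 1] + LUMA_WEIGHTS[2] * px[, , 2] +
    LUMA_WEIGHTS[3] * px[, , 3]
}

#' Detect filament boundary edges
#'
#' Applies Canny edge detection to the binarized image (or, optionally, to
#' the grayscale image). The single published threshold is interpreted as
#' the high hysteresis threshold, with the low threshold a fixed ratio of
#' it; both are fractions of the maximum gradient magnitude.
#'
#' @param x An H x W logical matrix from [to_binary()], or a numeric
#'   intensity matrix in \[0, 1\] (grayscale variant).
#' @param threshold High hysteresis threshold (default 0.3).
#' @param low_ratio Low threshold as a fraction of `threshold` (default 0.4).
#' @param sigma Gaussian pre-smoothing sigma in px.
#' @return An H x W logical edge map.
#' @export
detect_edges <- function(x, threshold = 0.3, low_ratio = 0.4, sigma = 1) {
  if (!is.matrix(x)) {
    it_stop("`x` must be a logical or numeric matrix.",
            "inktransition_invalid_input")
  }
  tie <- NULL
  if (is.logical(x)) {
    tie <- x * 1
    x <- x * 1
  }
  edges <- canny(x, high = threshold, low_ratio = low_ratio, sigma = sigma,
                 tie_break = tie)
  if (!any(edges)) {
    it_stop("No edges detected: no filament found in the image.",
            "inktransition_no_filament")
  }
  edges
}

#' Build the filament mask from an edge map
#'
#' For each image column the filament interior is taken as the rows strictly
#' between the outermost (first and last) edge pixels of that column;
#' columns with fewer than two edge pixels, or with no interior row, are
#' excluded.
#'
#' @param edge_map Logical H x W edge map from [detect_edges()].
#' @param min_columns Minimum number of covered columns below which the
#'   filament is considered too short to analyze.
#' @return An object of class `filament_mask` with components `mask`
#'   (logical H x W), `edge_map`, and `columns_covered` (sorted column
#'   indices).
#' @export
build_mask <- function(edge_map, min_columns = 5) {
  if (!is.matrix(edge_map) || !is.logical(edge_map) || !any(edge_map)) {
    it_stop("`edge_map` must be a nonempty logical matrix.",
            "inktransition_invalid_input")
  }
  H <- nrow(edge_map); W <- ncol(edge_map)
  mask <- matrix(FALSE, H, W)
  covered <- logical(W)
  for (cc in seq_len(W)) {
    idx <- which(edge_map[, cc])
    if (length(idx) >= 2) {
      top <- idx[1]; bot <- idx[length(idx)]
      if (bot - top >= 2) {
        mask[(top + 1):(bot - 1), cc] <- TRUE
        covered[cc] <- TRUE
      }
    }
  }
  cols <- which(covered)
  if (length(cols) < min_columns) {
    it_stop(sprintf("Filament too short: %d covered columns (minimum %d).",
                    length(cols), min_columns),
            "inktransition_filament_too_short")
  }
  structure(list(mask = mask, edge_map = edge_map, columns_covered = cols),
            class = "filament_mask")
}

#' Extract the along-filament color profile
#'
#' Averages each RGB channel over the mask pixels of every covered column,
#' then smooths the per-column means with a centered moving average
#' (see [moving_average()]; symmetric truncation at the profile ends). The
#' print direction is inferred from whether the smoothed red channel
#' decreases (`a_to_b`, red upstream) or increases (`b_to_a`) between the
#' profile ends; a difference below 1/255 leaves it `undetermined`.
#'
#' @param image The [raster_image()] the mask was derived from.
#' @param mask A [build_mask()] result.
#' @param window_px Moving-average window length in pixels (default 20).
#' @return An object of class `color_profile` with components
#'   `positions_px`, `mean_rgb` and `smoothed_rgb` (n x 3 matrices),
#'   `window_px`, `mm_per_px`, `direction`, plus the source `elapsed_s`,
#'   `condition` and `id`.
#' @export
extract_profile <- function(image, mask, window_px = 20) {
  if (!inherits(mask, "filament_mask")) {
    it_stop("`mask` must come from build_mask().", "inktransition_invalid_input")
  }
  cols <- mask$columns_covered
  if (length(cols) < window_px) {
    it_stop(sprintf("Filament too short: %d covered columns < window of %d.",
                    length(cols), window_px),
            "inktransition_filament_too_short")
  }
  m <- mask$mask * 1
  counts <- colSums(m)[cols]
  mean_rgb <- sapply(1:3, function(ch) {
    colSums(image$pixels[, , ch] * m)[cols] / counts
  })
  smoothed_rgb <- apply(mean_rgb, 2, moving_average, window = window_px)
  if (length(cols) == 1L) smoothed_rgb <- matrix(smoothed_rgb, nrow = 1)

  dr <- smoothed_rgb[1, 1] - smoothed_rgb[nrow(smoothed_rgb), 1]
  direction <- if (dr > 1 / 255) "a_to_b" else if (dr < -1 / 255) "b_to_a" else "undetermined"

  structure(list(
    positions_px = cols,
    mean_rgb = mean_rgb,
    smoothed_rgb = smoothed_rgb,
    window_px = window_px,
    mm_per_px = image$mm_per_px,
    direction = direction,
    elapsed_s = image$elapsed_s,
    condition = image$condition,
    id = image$id
  ), class = "color_profile")
}

#' @export
print.color_profile <- function(x, ...) {
  cat(sprintf("<color_profile> '%s': %d positions, window %d px, %g mm/px, direction %s\n",
              x$id, length(x$positions_px), x$window_px, x$mm_per_px, x$direction))
  invisible(x)
}

#' Measure a filament image end to end
#'
#' Convenience wrapper running the full pipeline: [to_binary()],
#' [detect_edges()], [build_mask()], [extract_profile()] and
#' [measure_transition()].
#'
#' @param image A [raster_image()].
#' @param window_px Moving-average window (default 20).
#' @param canny_high,canny_low_ratio,canny_sigma Edge-detection parameters.
#' @param binarize One of `"otsu"`, `"fixed"`, or `"none"`; `"none"` runs
#'   Canny on the grayscale image instead of the binarized one.
#' @param threshold Fixed luminance threshold when `binarize = "fixed"`.
#' @param min_columns Minimum covered columns for a valid filament.
#' @param ... Passed to [measure_transition()] (`hi`, `lo`,
#'   `uncertainty_floor_mm`, `subpixel`).
#' @return A `transition_result`; see [measure_transition()].
#' @export
measure_filament <- function(image, window_px = 20, canny_high = 0.3,
                             canny_low_ratio = 0.4, canny_sigma = 1,
                             binarize = c("otsu", "fixed", "none"),
                             threshold = NULL, min_columns = 5, ...) {
  binarize <- match.arg(binarize)
  src <- if (binarize == "none") {
    luminance(image)
  } else {
    to_binary(image, method = binarize, threshold = threshold)
  }
  edges <- detect_edges(src, threshold = canny_high,
                        low_ratio = canny_low_ratio, sigma = canny_sigma)
  mask <- build_mask(edges, min_columns = min_columns)
  profile <- extract_profile(image, mask, window_px = window_px)
  measure_transition(profile, ...)
}
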