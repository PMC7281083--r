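#' RGB raster image with physical scale and capture metadata
#'
#' The input container of the measurement pipeline: an H x W x 3 array of
#' intensities in \[0, 1\], the pixel scale in mm per pixel, and optionally
#' the elapsed time since printing (needed later for diffusion correction)
#' and the print condition the image belongs to.
#'
#' @param pixels Numeric H x W x 3 array with values in \[0, 1\]. A grayscale
#'   H x W matrix is promoted to three identical channels.
#' @param mm_per_px Physical scale, mm per pixel (> 0).
#' @param elapsed_s Time since printing in seconds, or `NA` if unknown.
#' @param condition Optional [print_condition()].
#' @param id Image label used in output records.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, mm_per_px, elapsed_s = NA_real_,
                         condition = NULL, id = "") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] < 3) {
    it_stop("`pixels` must be an H x W x 3 array.", "inktransition_invalid_input")
  }
  pixels <- pixels[, , 1:3, drop = FALSE] # drop alpha if present
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    it_stop("Pixel intensities must lie in [0, 1].", "inktransition_invalid_input")
  }
  if (!is_scalar_number(mm_per_px) || mm_per_px <= 0) {
    it_stop("`mm_per_px` must be a positive number.", "inktransition_invalid_input")
  }
  if (!is.null(condition)) {
    condition <- as_print_condition(condition)
  }
  structure(list(pixels = pixels, mm_per_px = mm_per_px,
                 elapsed_s = as.numeric(elapsed_s),
                 condition = condition, id = as.character(id)),
            class = "raster_image")
}

#' Read a filament photograph from PNG or TIFF
#'
#' Decodes 8- or 16-bit PNG/TIFF to \[0, 1\] intensities and attaches the
#' physical scale and capture metadata the pipeline needs.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param mm_per_px Physical scale of the image, mm per pixel.
#' @param elapsed_s Time since printing in seconds (`NA` if unknown).
#' @param condition Optional [print_condition()].
#' @param id Image label; defaults to the file name.
#' @param crop Optional integer vector `c(row0, col0, row1, col1)` selecting
#'   a sub-image (inclusive bounds) before analysis.
#' @param rotate One of 0, 90, 180, 270: clockwise rotation applied after
#'   reading, so that the filament runs left to right in print order.
#' @return A [raster_image()].
#' @export
read_filament_image <- function(path, mm_per_px, elapsed_s = NA_real_,
                                condition = NULL, id = basename(path),
                                crop = NULL, rotate = 0) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               it_stop(sprintf("Unsupported image format '.%s' (PNG or TIFF expected).", ext),
                       "inktransition_invalid_input"))
  if (is.matrix(px)) px <- array(rep(px, 3), dim = c(dim(px), 3))
  px <- px[, , 1:3, drop = FALSE]
  if (!rotate %in% c(0, 90, 180, 270)) {
    it_stop("`rotate` must be one of 0, 90, 180, 270.", "inktransition_invalid_input")
  }
  for (k in seq_len(rotate / 90)) {
    px <- rotate_cw(px)
  }
  if (!is.null(crop)) {
    if (length(crop) != 4) {
      it_stop("`crop` must be c(row0, col0, row1, col1).", "inktransition_invalid_input")
    }
    px <- px[crop[1]:crop[3], crop[2]:crop[4], , drop = FALSE]
  }
  raster_image(px, mm_per_px = mm_per_px, elapsed_s = elapsed_s,
               condition = condition, id = id)
}

# Rotate an H x W x 3 array 90 degrees clockwise.
rotate_cw <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  out <- array(0, dim = c(W, H, 3))
  for (ch in 1:3) {
    out[, , ch] <- t(px[H:1, , ch])
  }
  out
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> '%s' %d x %d px, %g mm/px, elapsed %s s\n",
              x$id, d[1], d[2], x$mm_per_px,
              ifelse(is.na(x$elapsed_s), "?", format(x$elapsed_s))))
  invisible(x)
}
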