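#' Specification of a synthetic two-ink filament image
#'
#' Describes a straight, horizontal filament of two dyed bioinks (upstream
#' ink `color_a`, downstream ink `color_b`) on a plain background, with a
#' color transition of known analytic 90-10 width. The apparent transition
#' widens with elapsed time after printing according to `growth_law`,
#' emulating dye diffusion within the deposited filament; the default growth
#' rate is the empirically fitted 0.03060 mm/s linear law used for the
#' diffusion correction.
#'
#' Axial positions are 1-based column indices of the image; the physical
#' scale is `mm_per_px` millimetres per pixel.
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param filament_width_px Vertical extent of the filament band, px.
#' @param filament_center_row_px Row of the band center.
#' @param mm_per_px Physical scale, mm per pixel (> 0).
#' @param color_a,color_b,background RGB triples in \[0, 1\]. Defaults are a
#'   red ink, a blue ink and a near-white background.
#' @param profile_kind One of `"step"`, `"linear_ramp"`, `"gaussian_cdf"`:
#'   the shape of the axial color-mixing profile.
#' @param transition_center_px Column at which the mixing fraction is 0.5.
#' @param profile_param Ramp length L in px (`linear_ramp`) or spread sigma
#'   in px (`gaussian_cdf`); ignored for `step`.
#' @param elapsed_s Time since printing, seconds (>= 0).
#' @param growth_law One of `"none"`, `"linear"`, `"sqrt"`: how the 90-10
#'   width grows with elapsed time.
#' @param growth_coeff Growth rate, mm/s (`linear`) or mm/sqrt(s) (`sqrt`).
#' @param noise_sigma Standard deviation of i.i.d. per-channel Gaussian
#'   pixel noise, intensity units (>= 0).
#' @param edge_softness_px Width of the soft roll-off at the band's top and
#'   bottom boundaries, px (0 = hard edges).
#' @param seed Integer seed; identical specs with identical seeds render
#'   bitwise-identical images.
#' @return An object of class `filament_spec`.
#' @seealso [generate_filament_image()], [mixing_fraction()]
#' @export
filament_spec <- function(image_height_px = 200,
                          image_width_px = 600,
                          filament_width_px = 60,
                          filament_center_row_px = 100,
                          mm_per_px = 0.05,
                          color_a = c(0.85, 0.10, 0.10),
                          color_b = c(0.10, 0.10, 0.75),
                          background = c(0.97, 0.97, 0.97),
                          profile_kind = c("gaussian_cdf", "step", "linear_ramp"),
                          transition_center_px = image_width_px / 2,
                          profile_param = 10,
                          elapsed_s = 0,
                          growth_law = c("linear", "none", "sqrt"),
                          growth_coeff = 0.03060,
                          noise_sigma = 0.01,
                          edge_softness_px = 0,
                          seed = 1L) {
  profile_kind <- match.arg(profile_kind)
  growth_law <- match.arg(growth_law)

  spec <- structure(list(
    image_height_px = image_height_px,
    image_width_px = image_width_px,
    filament_width_px = filament_width_px,
    filament_center_row_px = filament_center_row_px,
    mm_per_px = mm_per_px,
    color_a = color_a,
    color_b = color_b,
    background = background,
    profile_kind = profile_kind,
    transition_center_px = transition_center_px,
    profile_param = profile_param,
    elapsed_s = elapsed_s,
    growth_law = growth_law,
    growth_coeff = growth_coeff,
    noise_sigma = noise_sigma,
    edge_softness_px = edge_softness_px,
    seed = as.integer(seed)
  ), class = "filament_spec")
  validate_filament_spec(spec)
  spec
}

validate_filament_spec <- function(spec) {
  if (!inherits(spec, "filament_spec")) {
    it_stop("Not a `filament_spec` object.", "inktransition_invalid_spec")
  }
  with(spec, {
    if (!is_count(image_height_px) || !is_count(image_width_px) ||
        !is_count(filament_width_px)) {
      it_stop("Image and band dimensions must be positive integers.",
              "inktransition_invalid_spec")
    }
    if (!is_scalar_number(mm_per_px) || mm_per_px <= 0) {
      it_stop("`mm_per_px` must be a positive number.",
              "inktransition_invalid_spec")
    }
    if (!is_rgb(color_a) || !is_rgb(color_b) || !is_rgb(background)) {
      it_stop("Colors must be RGB triples with components in [0, 1].",
              "inktransition_invalid_spec")
    }
    if (!profile_kind %in% c("step", "linear_ramp", "gaussian_cdf")) {
      it_stop(sprintf("Unknown profile_kind '%s'.", profile_kind),
              "inktransition_invalid_spec")
    }
    if (!is_scalar_number(transition_center_px) ||
        transition_center_px < 1 || transition_center_px > image_width_px) {
      it_stop("`transition_center_px` must lie within the image columns.",
              "inktransition_invalid_spec")
    }
    if (profile_kind != "step" &&
        (!is_scalar_number(profile_param) || profile_param <= 0)) {
      it_stop("`profile_param` must be > 0 for ramp and gaussian profiles.",
              "inktransition_invalid_spec")
    }
    if (!is_scalar_number(elapsed_s) || elapsed_s < 0) {
      it_stop("`elapsed_s` must be >= 0.", "inktransition_invalid_spec")
    }
    if (!growth_law %in% c("none", "linear", "sqrt")) {
      it_stop(sprintf("Unknown growth_law '%s'.", growth_law),
              "inktransition_invalid_spec")
    }
    if (growth_law != "none" &&
        (!is_scalar_number(growth_coeff) || growth_coeff < 0)) {
      it_stop("`growth_coeff` must be >= 0.", "inktransition_invalid_spec")
    }
    if (!is_scalar_number(noise_sigma) || noise_sigma < 0) {
      it_stop("`noise_sigma` must be >= 0.", "inktransition_invalid_spec")
    }
    if (!is_scalar_number(edge_softness_px) || edge_softness_px < 0) {
      it_stop("`edge_softness_px` must be >= 0.", "inktransition_invalid_spec")
    }
    half <- filament_width_px / 2
    if (filament_center_row_px - half < 0.5 ||
        filament_center_row_px + half > image_height_px + 0.5) {
      it_stop("Filament band must lie fully inside the image.",
              "inktransition_invalid_spec")
    }
  })
  invisible(spec)
}

# Growth-law widening of the 90-10 width, in pixels.
growth_widening_px <- function(spec) {
  dw_mm <- switch(spec$growth_law,
                  none = 0,
                  linear = spec$growth_coeff * spec$elapsed_s,
                  sqrt = spec$growth_coeff * sqrt(spec$elapsed_s))
  dw_mm / spec$mm_per_px
}

# Base (elapsed_s = 0) 90-10 width in pixels, closed form per profile kind.
base_width_px <- function(spec) {
  switch(spec$profile_kind,
         step = 0,
         linear_ramp = 0.8 * spec$profile_param,
         gaussian_cdf = span_90_10_per_sigma() * spec$profile_param)
}

# Effective profile after additive widening of the 90-10 width. A step that
# must widen is rendered as a linear ramp whose 90-10 width equals the
# widening, keeping the ground truth closed-form.
effective_profile <- function(spec) {
  dw <- growth_widening_px(spec)
  kind <- spec$profile_kind
  param <- spec$profile_param
  if (kind == "step" && dw > 0) {
    kind <- "linear_ramp"
    param <- dw / 0.8
  } else if (kind == "linear_ramp") {
    param <- param + dw / 0.8
  } else if (kind == "gaussian_cdf") {
    param <- param + dw / span_90_10_per_sigma()
  }
  list(kind = kind, param = param)
}

#' Ground-truth mixing fraction along the filament axis
#'
#' Returns g(x), the fraction of the upstream ink `color_a` at axial
#' position `x` (pixels), after applying the growth law of `spec` to the
#' profile width: a step indicator, a clamped linear descent over the
#' effective ramp length, or the complementary normal CDF with the
#' effective spread. g is monotone non-increasing in x.
#'
#' @param x Numeric vector of axial positions (px, 1-based columns).
#' @param spec A [filament_spec()].
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
mixing_fraction <- function(x, spec) {
  validate_filament_spec(spec)
  eff <- effective_profile(spec)
  center <- spec$transition_center_px
  switch(eff$kind,
         step = as.numeric(x < center),
         linear_ramp = clamp01(0.5 - (x - center) / eff$param),
         gaussian_cdf = 1 - stats::pnorm((x - center) / eff$param))
}

#' Generate a synthetic filament image with known transition width
#'
#' Renders the filament band of `spec` (colors blended by
#' [mixing_fraction()], background elsewhere, optionally soft band edges),
#' adds i.i.d. Gaussian pixel noise, clips to \[0, 1\], and returns the image
#' together with the closed-form ground-truth 90-10 transition width after
#' growth-law widening. The generator is deterministic for a fixed spec and
#' seed.
#'
#' @param spec A [filament_spec()].
#' @return A list with components `image` (a [raster_image()]) and `truth`
#'   (class `filament_truth`: `true_width_90_10_px`, `true_width_90_10_mm`,
#'   `transition_center_px`, `direction`).
#' @export
generate_filament_image <- function(spec) {
  validate_filament_spec(spec)
  H <- spec$image_height_px
  W <- spec$image_width_px

  g <- mixing_fraction(seq_len(W), spec)

  w <- spec$filament_width_px
  r0 <- spec$filament_center_row_px - floor((w - 1) / 2)
  r1 <- r0 + w - 1
  rows <- seq_len(H)
  s <- spec$edge_softness_px
  if (s > 0) {
    alpha <- clamp01((rows - (r0 - 0.5)) / s) * clamp01(((r1 + 0.5) - rows) / s)
  } else {
    alpha <- as.numeric(rows >= r0 & rows <= r1)
  }

  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    ink <- g * spec$color_a[ch] + (1 - g) * spec$color_b[ch] # length W
    # outer(alpha, ink) blends band color over background per pixel
    px[, , ch] <- outer(alpha, ink) + outer(1 - alpha, rep(spec$background[ch], W))
  }

  if (spec$noise_sigma > 0) {
    px <- withr::with_seed(spec$seed, {
      px + stats::rnorm(length(px), sd = spec$noise_sigma)
    })
    px <- clamp01(px)
  }

  width_px <- base_width_px(spec) + growth_widening_px(spec)
  truth <- structure(list(
    true_width_90_10_px = width_px,
    true_width_90_10_mm = width_px * spec$mm_per_px,
    transition_center_px = spec$transition_center_px,
    direction = "a_to_b"
  ), class = "filament_truth")

  img <- raster_image(px, mm_per_px = spec$mm_per_px,
                      elapsed_s = spec$elapsed_s,
                      id = sprintf("synthetic-seed%d", spec$seed))
  list(image = img, truth = truth)
}

#' Write a synthetic image to PNG with a ground-truth sidecar
#'
#' Writes the rendered image as 8-bit RGB PNG and a JSON sidecar holding the
#' generating spec and the closed-form ground-truth widths, so that
#' downstream measurements can be validated against the file pair alone.
#'
#' @param spec A [filament_spec()].
#' @param path Output PNG path; the sidecar is written to `<path>.json`.
#' @return Invisibly, the list returned by [generate_filament_image()].
#' @export
write_filament_image <- function(spec, path) {
  gen <- generate_filament_image(spec)
  png::writePNG(gen$image$pixels, target = path)
  sidecar <- c(unclass(spec),
               list(true_width_90_10_px = gen$truth$true_width_90_10_px,
                    true_width_90_10_mm = gen$truth$true_width_90_10_mm))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(gen)
}

#' @export
print.filament_spec <- function(x, ...) {
  cat(sprintf(
    "<filament_spec> %dx%d px, band %d px @ row %g, %s profile (param %g px)\n",
    x$image_height_px, x$image_width_px, x$filament_width_px,
    x$filament_center_row_px, x$profile_kind, x$profile_param))
  cat(sprintf("  scale %g mm/px; growth %s (%g), elapsed %g s; noise sd %g; seed %d\n",
              x$mm_per_px, x$growth_law, x$growth_coeff, x$elapsed_s,
              x$noise_sigma, x$seed))
  invisible(x)
}

#' @export
print.filament_truth <- function(x, ...) {
  cat(sprintf("<filament_truth> 90-10 width %.3f px = %.4f mm, center %g px (%s)\n",
              x$true_width_90_10_px, x$true_width_90_10_mm,
              x$transition_center_px, x$direction))
  invisible(x)
}
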