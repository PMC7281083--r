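# Shared fixture builders: noiseless, growth-free specs centered in a wide
# image so the profile reaches both plateaus.

quiet_spec <- function(kind = "gaussian_cdf", param = 10, width = 360,
                       noise = 0, seed = 1L, ...) {
  filament_spec(profile_kind = kind, profile_param = param,
                image_width_px = width, transition_center_px = width / 2,
                noise_sigma = noise, growth_law = "none", seed = seed, ...)
}

# Render a spec at `factor` times the spatial resolution (same physical
# scene: all pixel quantities scaled, mm_per_px divided).
rescale_spec <- function(spec, factor) {
  s <- unclass(spec)
  s$image_height_px <- s$image_height_px * factor
  s$image_width_px <- s$image_width_px * factor
  s$filament_width_px <- s$filament_width_px * factor
  s$filament_center_row_px <- s$filament_center_row_px * factor
  s$transition_center_px <- s$transition_center_px * factor
  s$profile_param <- s$profile_param * factor
  s$edge_softness_px <- s$edge_softness_px * factor
  s$mm_per_px <- s$mm_per_px / factor
  do.call(filament_spec, s)
}

# Pipeline up to the color profile.
profile_of <- function(image, window_px = 20) {
  mask <- build_mask(detect_edges(to_binary(image)))
  extract_profile(image, mask, window_px = window_px)
}
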