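# Normalization, crossing location and the 90-10 distance statistic.

test_that("normalization maps the profile onto [0, 1] and is affine invariant", {
  s <- quiet_spec("gaussian_cdf", param = 10)
  img <- generate_filament_image(s)$image
  p <- profile_of(img, window_px = 1)
  rn <- normalize_red(p)
  expect_equal(max(rn), 1)
  expect_equal(min(rn), 0)

  # affine rescaling of the red channel leaves r_norm unchanged
  p2 <- p
  p2$smoothed_rgb[, 1] <- 0.4 * p$smoothed_rgb[, 1] + 0.17
  expect_equal(normalize_red(p2), rn, tolerance = 1e-12)

  # value at the transition center is 0.5 (g = pnorm(0) mapped through the blend)
  i <- which(p$positions_px == s$transition_center_px)
  expect_equal(rn[i], 0.5, tolerance = 0.01)

  # flat profile errors
  p3 <- p
  p3$smoothed_rgb[, 1] <- 0.3
  expect_error(normalize_red(p3), class = "inktransition_no_transition")
})

test_that("crossings on a unit ramp solve the 0.9/0.1 levels exactly", {
  # linear descent 1 -> 0 over 101 samples: 90-10 span = 0.8 * 100
  r <- seq(1, 0, length.out = 101)
  cr <- find_crossings(r, seq_len(101))
  expect_equal(cr$end_px - cr$start_px, 80, tolerance = 1e-10)

  # degenerate thresholds: distance -> 0 as hi - lo -> 0
  d <- sapply(c(0.2, 0.05, 0.01), function(eps) {
    cr <- find_crossings(r, seq_len(101), hi = 0.5 + eps / 2, lo = 0.5 - eps / 2)
    cr$end_px - cr$start_px
  })
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 1.1)

  # failure modes name the failing bound
  expect_error(find_crossings(seq(1, 0.5, length.out = 20), 1:20),
               class = "inktransition_no_transition")
  expect_error(find_crossings(seq(0.5, 0, length.out = 20), 1:20),
               class = "inktransition_no_transition")
})

test_that("an ideal step smoothed with window 20 measures exactly 16 px", {
  s <- quiet_spec("step", width = 300)
  img <- generate_filament_image(s)$image
  res <- measure_filament(img, window_px = 20)
  expect_equal(res$distance_px, 16, tolerance = 1e-9)
})

test_that("distance converts to mm by the pixel scale", {
  s <- quiet_spec("gaussian_cdf", param = 10, mm_per_px = 0.05)
  img <- generate_filament_image(s)$image
  res <- measure_filament(img, window_px = 1)
  expect_equal(res$distance_mm, res$distance_px * 0.05)
  expect_lt(abs(res$distance_mm - 2 * qnorm(0.9) * 10 * 0.05), 0.05) # 1 px in mm
  # uncertainty: max of the 0.02 mm floor and one pixel
  expect_equal(res$uncertainty_mm, 0.05)
  s2 <- quiet_spec("gaussian_cdf", param = 10, mm_per_px = 0.005)
  res2 <- measure_filament(generate_filament_image(s2)$image, window_px = 1)
  expect_equal(res2$uncertainty_mm, 0.02)

  # unit scale: mm numerically equals px
  s3 <- quiet_spec("gaussian_cdf", param = 10, mm_per_px = 1)
  res3 <- measure_filament(generate_filament_image(s3)$image, window_px = 1)
  expect_equal(res3$distance_mm, res3$distance_px)
})

test_that("measured widths recover the ground truth across shapes and noise", {
  for (sigma in c(5, 10, 20, 40)) {
    for (noise in c(0, 0.01, 0.03)) {
      s <- quiet_spec("gaussian_cdf", param = sigma, width = 400,
                      noise = noise, seed = 100L + sigma)
      gen <- generate_filament_image(s)
      res <- measure_filament(gen$image, window_px = 20)
      tol <- 0.05 * gen$truth$true_width_90_10_mm + 0.8 * 20 * s$mm_per_px
      expect_lt(abs(res$distance_mm - gen$truth$true_width_90_10_mm), tol)
      if (noise == 0) {
        # noiseless, unsmoothed: sub-pixel agreement
        res1 <- measure_filament(gen$image, window_px = 1)
        expect_lt(abs(res1$distance_px - gen$truth$true_width_90_10_px), 0.5)
      }
    }
  }
})

test_that("swapping the ink colors changes the distance by less than a pixel", {
  s1 <- quiet_spec("gaussian_cdf", param = 12, noise = 0.01, seed = 5L)
  s2 <- quiet_spec("gaussian_cdf", param = 12, noise = 0.01, seed = 5L,
                   color_a = c(0.10, 0.10, 0.75), color_b = c(0.85, 0.10, 0.10))
  r1 <- measure_filament(generate_filament_image(s1)$image)
  r2 <- measure_filament(generate_filament_image(s2)$image)
  expect_equal(r1$direction, "a_to_b")
  expect_equal(r2$direction, "b_to_a")
  expect_lt(abs(r1$distance_px - r2$distance_px), 1)
})

test_that("distance is monotone in the profile spread", {
  d <- sapply(c(5, 10, 20, 40), function(sigma) {
    s <- quiet_spec("gaussian_cdf", param = sigma, width = 400)
    measure_filament(generate_filament_image(s)$image, window_px = 1)$distance_px
  })
  expect_true(all(diff(d) > 0))
})

test_that("sub-pixel interpolation stays within a pixel of the sample answer", {
  s <- quiet_spec("gaussian_cdf", param = 10, noise = 0.01, seed = 3L)
  img <- generate_filament_image(s)$image
  p <- profile_of(img)
  sub <- measure_transition(p, subpixel = TRUE)
  pix <- measure_transition(p, subpixel = FALSE)
  expect_lt(abs(sub$start_px - pix$start_px), 1)
  expect_lt(abs(sub$end_px - pix$end_px), 1)
  expect_lt(abs(sub$distance_px - pix$distance_px), 2)
})

test_that("doubling the resolution leaves the physical distance unchanged", {
  s1 <- quiet_spec("gaussian_cdf", param = 10, width = 300)
  s2 <- rescale_spec(s1, 2)
  r1 <- measure_filament(generate_filament_image(s1)$image, window_px = 1)
  r2 <- measure_filament(generate_filament_image(s2)$image, window_px = 1)
  expect_equal(r2$distance_px / r1$distance_px, 2, tolerance = 0.05)
  expect_lt(abs(r2$distance_mm - r1$distance_mm), s1$mm_per_px)
})

test_that("transition_table flattens results with condition fields", {
  s <- quiet_spec()
  img <- generate_filament_image(s)$image
  img$condition <- print_condition(45, 430, coated = FALSE)
  img$id <- "img-1"
  res <- measure_filament(img)
  tab <- transition_table(list(res, res))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pressure_psi, c(45, 45))
  expect_equal(tab$nozzle_id_um, c(430, 430))
  expect_equal(tab$distance_mm, rep(res$distance_mm, 2))
})
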