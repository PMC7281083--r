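# Per-condition aggregation and trend diagnostics.

# Minimal result carrying only what aggregation reads.
fake_result <- function(mm, pressure, nozzle, coated = FALSE, corrected = NA_real_,
                        flags = character(), id = "x") {
  structure(list(start_px = 0, end_px = mm / 0.05, distance_px = mm / 0.05,
                 distance_mm = mm, corrected_mm = corrected,
                 uncertainty_mm = 0.05, direction = "a_to_b", flags = flags,
                 mm_per_px = 0.05, elapsed_s = 0,
                 condition = print_condition(pressure, nozzle, coated),
                 id = id),
            class = "transition_result")
}

test_that("summaries reproduce hand arithmetic and handle n = 1", {
  res <- list(fake_result(10, 45, 430), fake_result(12, 45, 430),
              fake_result(14, 45, 430), fake_result(7.5, 25, 250, coated = TRUE))
  s <- summarize_conditions(res)
  expect_equal(nrow(s), 2)
  # deterministic ordering: pressure first
  expect_equal(s$pressure_psi, c(25, 45))
  row <- s[s$pressure_psi == 45, ]
  expect_equal(row$n, 3L)
  expect_equal(row$mean_mm, 12)
  expect_equal(row$sd_mm, 2)
  expect_equal(row$min_mm, 10)
  expect_equal(row$max_mm, 14)
  one <- s[s$pressure_psi == 25, ]
  expect_equal(one$sd_mm, 0)
  expect_equal(one$min_mm, one$max_mm)
  expect_equal(one$min_mm, one$mean_mm)
})

test_that("empty input yields an empty summary, not an error", {
  s <- summarize_conditions(list())
  expect_s3_class(s, "tbl_df")
  expect_equal(nrow(s), 0)
})

test_that("flagged results are excluded by default and kept on request", {
  res <- list(fake_result(10, 45, 430),
              fake_result(99, 45, 430, flags = "clipped_at_boundary"))
  expect_equal(summarize_conditions(res)$n, 1L)
  expect_equal(summarize_conditions(res, include_flagged = TRUE)$n, 2L)
})

test_that("corrected summaries require every result to be corrected", {
  res <- list(fake_result(10, 45, 430, corrected = 9.1),
              fake_result(12, 45, 430))
  expect_error(summarize_conditions(res, use_corrected = TRUE),
               class = "inktransition_invalid_input")
  res2 <- list(fake_result(10, 45, 430, corrected = 9.1),
               fake_result(12, 45, 430, corrected = 11.3))
  s <- summarize_conditions(res2, use_corrected = TRUE)
  expect_equal(s$mean_mm, (9.1 + 11.3) / 2)
  expect_true(all(s$used_corrected))
})

test_that("summaries are invariant under permutation of the input", {
  set.seed(21)
  res <- lapply(1:30, function(i) {
    fake_result(runif(1, 5, 20), sample(c(25, 35, 45), 1),
                sample(c(250, 330, 430), 1), coated = runif(1) < 0.5,
                id = paste0("img", i))
  })
  s1 <- summarize_conditions(res)
  s2 <- summarize_conditions(res[sample(length(res))])
  expect_equal(s1, s2)
})

test_that("batch summaries pool to the summary of the concatenation", {
  set.seed(8)
  a <- lapply(1:7, function(i) fake_result(runif(1, 5, 20), 45, 430))
  b <- lapply(1:5, function(i) fake_result(runif(1, 5, 20), 45, 430))
  sa <- summarize_conditions(a); sb <- summarize_conditions(b)
  sc <- summarize_conditions(c(a, b))
  n <- sa$n + sb$n
  mean_pool <- (sa$n * sa$mean_mm + sb$n * sb$mean_mm) / n
  ss_pool <- (sa$n - 1) * sa$sd_mm^2 + (sb$n - 1) * sb$sd_mm^2 +
    sa$n * sb$n / n * (sa$mean_mm - sb$mean_mm)^2
  expect_equal(sc$n, n)
  expect_equal(sc$mean_mm, mean_pool)
  expect_equal(sc$sd_mm, sqrt(ss_pool / (n - 1)))
  expect_equal(sc$min_mm, pmin(sa$min_mm, sb$min_mm))
  expect_equal(sc$max_mm, pmax(sa$max_mm, sb$max_mm))
})

test_that("per-condition means follow the generating order in a synthetic sweep", {
  # ground-truth width increases with the "pressure" covariate
  res <- list()
  for (p in c(25, 35, 45)) {
    for (i in 1:2) {
      s <- quiet_spec("gaussian_cdf", param = p / 2.5, width = 400,
                      noise = 0.01, seed = as.integer(1000 + p + i))
      img <- generate_filament_image(s)$image
      img$condition <- print_condition(p, 430)
      res <- c(res, list(measure_filament(img)))
    }
  }
  s <- summarize_conditions(res)
  expect_true(all(diff(s$mean_mm) > 0))
})

test_that("trend slopes match the construction and a normal-equations oracle", {
  # exact increasing line: slope recovered exactly
  res <- lapply(c(25, 35, 45, 55), function(p) fake_result(2 + 0.3 * p, p, 430))
  tr <- trend_report(summarize_conditions(res))
  expect_equal(tr$pressure_trends$slope_mm_per_psi, 0.3, tolerance = 1e-12)

  # flat summaries: zero slope
  res_f <- lapply(c(25, 35, 45), function(p) fake_result(9, p, 330))
  tr_f <- trend_report(summarize_conditions(res_f))
  expect_equal(tr_f$pressure_trends$slope_mm_per_psi, 0, tolerance = 1e-12)

  # randomized design vs explicit normal equations
  set.seed(4)
  res_r <- list()
  for (p in c(25, 35, 45, 55)) {
    res_r <- c(res_r, list(fake_result(runif(1, 5, 20), p, 250, coated = TRUE)))
  }
  s <- summarize_conditions(res_r)
  tr_r <- trend_report(s)
  x <- s$pressure_psi; y <- s$mean_mm
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tr_r$pressure_trends$slope_mm_per_psi, beta, tolerance = 1e-12)

  # insufficient levels: NA slope, not an error
  tr_one <- trend_report(summarize_conditions(list(fake_result(9, 45, 430))))
  expect_true(is.na(tr_one$pressure_trends$slope_mm_per_psi))
})

test_that("nozzle trends split by coating recover opposite signs", {
  res <- list()
  for (nz in c(250, 330, 430)) {
    # coated: distance grows with nozzle; regular: shrinks with nozzle
    res <- c(res, list(fake_result(nz / 50, 45, nz, coated = TRUE),
                       fake_result(20 - nz / 50, 45, nz, coated = FALSE)))
  }
  tr <- trend_report(summarize_conditions(res))
  nt <- tr$nozzle_trends
  expect_gt(nt$slope_mm_per_um[nt$coated], 0)
  expect_lt(nt$slope_mm_per_um[!nt$coated], 0)
})

test_that("the summary plot is a well-formed ggplot", {
  res <- lapply(c(25, 35), function(p) fake_result(2 + 0.3 * p, p, 430))
  pl <- plot_condition_summaries(summarize_conditions(res))
  expect_s3_class(pl, "ggplot")
})
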