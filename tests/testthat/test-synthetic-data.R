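test_that("chromatogram generator honours the linear response model", {
  m0 <- response_model(slope = 50, intercept = 0, injection_cv = 0)

  # zero concentration, no noise, no intercept: flat trace, zero area
  flat <- generate_chromatogram(0, m0, noise_sd = 0)
  expect_true(all(flat$signal == 0))
  expect_identical(attr(flat, "true_area"), 0)

  # identity of the linear model: conc 100 at slope 50 gives area 5000
  ch <- generate_chromatogram(100, m0, noise_sd = 0)
  expect_equal(attr(ch, "true_area"), 5000)
  expect_equal(pracma::trapz(ch$time_min, ch$signal), 5000, tolerance = 5e-3)

  # preconditions
  expect_error(generate_chromatogram(100, m0, sampling_rate = -1),
               class = "caffval_invalid_argument")
  expect_error(generate_chromatogram(100, m0, sampling_rate = 1),
               class = "caffval_invalid_argument")
})

test_that("replicate trace areas average to the model response (Monte Carlo)", {
  m <- response_model(slope = 50, intercept = 0, injection_cv = 0.02,
                      retention_time = 1)
  n <- 400
  areas <- vapply(seq_len(n), function(i) {
    ch <- generate_chromatogram(100, m, noise_sd = 0.5, duration = 2, seed = 1000 + i)
    measure_peak_area(ch, 1)$area
  }, numeric(1))
  se <- sd(areas) / sqrt(n)
  expect_lt(abs(mean(areas) - 5000), 3 * se + 0.005 * 5000)
  # configured CV is recovered (integration adds little extra variance)
  expect_equal(sd(areas) / mean(areas), 0.02, tolerance = 3 / sqrt(n) * 5)
})

test_that("calibration set generation is exact without noise and reproducible", {
  m0 <- response_model(slope = 50, intercept = 10, injection_cv = 0)
  levels <- c(10, 50, 100, 500, 1000)
  cal <- generate_calibration_set(levels, m0, seed = 1)
  expect_equal(cal$response, 50 * sort(levels) + 10)

  m <- response_model()
  expect_identical(generate_calibration_set(model = m, seed = 7),
                   generate_calibration_set(model = m, seed = 7))
  expect_error(generate_calibration_set(rep(100, 6), m),
               class = "caffval_degenerate_design")
})

test_that("noisy calibration refit recovers the true slope within 3 SE", {
  m <- response_model(slope = 50, injection_cv = 0.02)
  cal <- generate_calibration_set(model = m, seed = 11)
  fit <- fit_calibration(cal)
  expect_lt(abs(fit$slope - 50), 3 * fit$se_slope)
})

test_that("validation study generator matches its generative model", {
  # no variability, perfect recovery: measurements are exactly background+spike
  d0 <- ref_design(true_recovery_per_level = 1, within_day_cv = 0,
                   between_day_cv = 0, seed = 1)
  st0 <- generate_validation_study(d0)
  fort <- dplyr::filter(st0, spike_pct > 0)
  expect_equal(fort$measured_pct, 1.3 + fort$spike_pct)

  # configured recovery, no noise: spike contribution scales by recovery
  d1 <- ref_design(true_recovery_per_level = c(0.935, 0.967, 1.020),
                   within_day_cv = 0, between_day_cv = 0, seed = 1)
  st1 <- generate_validation_study(d1)
  lvl05 <- dplyr::filter(st1, spike_pct == 0.5)
  expect_equal(unique(lvl05$measured_pct) - 1.3, 0.4675)

  # determinism under a fixed seed
  d <- ref_design(seed = 99)
  expect_identical(as.data.frame(generate_validation_study(d)),
                   as.data.frame(generate_validation_study(d)))
})

test_that("study CV estimates converge to configured components at large n", {
  # many days and replicates so both variance components are well estimated
  d <- ref_design(spike_levels = 1.0, true_recovery_per_level = 1,
                  within_day_cv = 0.041, between_day_cv = 0.02,
                  days = 60, replicates_per_day = 30, n_blanks = 0, seed = 5)
  st <- generate_validation_study(d)
  ps <- precision_summary(st, 1.0, background = 1.3)
  expect_equal(ps$rsd_r, 4.1, tolerance = 0.1)
  expect_equal(ps$rsd_R, 100 * sqrt(0.041^2 + 0.02^2), tolerance = 0.15)
})

test_that("QC series generator: determinism, constancy, and tail fraction", {
  expect_equal(generate_qc_series(5, 2.3, 0, seed = 1)$measured_pct, rep(2.3, 5))
  expect_identical(generate_qc_series(20, 2.3, 0.03, seed = 3),
                   generate_qc_series(20, 2.3, 0.03, seed = 3))
  # run indices spaced 5 apart
  expect_equal(generate_qc_series(4, 2.3, 0, seed = 1)$run_index, c(5, 10, 15, 20))

  qc <- generate_qc_series(10000, 2.3, 0.03, seed = 8)
  beyond <- mean(abs(qc$measured_pct - 2.3) > 2 * 2.3 * 0.03)
  expect_equal(beyond, 2 * pnorm(-2), tolerance = 0.25) # ~4.55 % +/- MC error

  # injected shifts are recorded as ground truth
  qs <- generate_qc_series(10, 2.3, 0.03, outlier_spec = list(at = 4, shift_sd = 5),
                           seed = 2)
  expect_true(qs$shifted[4] && sum(qs$shifted) == 1)
})

test_that("chromatogram CSV round trip preserves the trace", {
  ch <- generate_chromatogram(50, response_model(retention_time = 1),
                              noise_sd = 0.2, duration = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram_csv(ch, path)
  back <- read_chromatogram_csv(path)
  expect_equal(back$time_min, ch$time_min)
  expect_equal(back$signal, ch$signal)
})
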