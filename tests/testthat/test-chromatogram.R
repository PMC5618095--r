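test_that("baseline estimation tracks flat, offset and drifting baselines", {
  tt <- seq(0, 2, by = 1 / 1500)
  expect_equal(estimate_baseline(chrom_from(tt, rep(0, length(tt)))),
               rep(0, length(tt)))
  expect_equal(estimate_baseline(chrom_from(tt, rep(7, length(tt)))),
               rep(7, length(tt)))

  # Gaussian peak on a linear drift, noise-free: baseline recovers the drift
  # outside the peak region (morphological opening is exact on monotone drift).
  # Edge replication biases the estimate within window/2 + the smoothing
  # half-window = 0.4 min of the record ends, so those points are excluded.
  drift <- 3 + 2 * tt
  peak <- gauss_trace(A = 5000, rt = 1, sigma = 0.02)$signal
  b <- estimate_baseline(chrom_from(tt, drift + peak), window = 0.4)
  outside <- abs(tt - 1) > 0.35 & tt > 0.4 & tt < 1.6 # away from peak and edges
  expect_lt(max(abs(b[outside] - drift[outside])), 0.05)

  # with noise the recovered drift stays within a few noise SDs
  set.seed(42)
  noisy <- drift + peak + rnorm(length(tt), 0, 0.5)
  bn <- estimate_baseline(chrom_from(tt, noisy), window = 0.4)
  expect_lt(max(abs(bn[outside] - drift[outside])), 3 * 0.5)

  expect_error(estimate_baseline(gauss_trace(), window = 10),
               class = "caffval_invalid_argument")
  expect_error(estimate_baseline(gauss_trace(), window = 1e-9),
               class = "caffval_invalid_argument")
})

test_that("peak detection finds injected peaks and nothing else", {
  tt <- seq(0, 2, by = 1 / 1500)
  expect_equal(nrow(detect_peaks(chrom_from(tt, rep(0, length(tt))), 1)), 0)

  # one Gaussian with amplitude 10x the threshold: exactly one peak at the apex
  g <- gauss_trace(A = 100, rt = 1, sigma = 0.02) # amplitude ~1995
  pk <- detect_peaks(g, min_height = 199.5)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$apex_time - 1), 1 / 1500 + 1e-12)

  # two well-separated Gaussians, returned in time order
  s2 <- gauss_trace(A = 100, rt = 0.6)$signal + gauss_trace(A = 200, rt = 1.4)$signal
  pk2 <- detect_peaks(chrom_from(tt, s2), min_height = 100)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$apex_time[1] - 0.6), 0.005)
  expect_lt(abs(pk2$apex_time[2] - 1.4), 0.005)
})

test_that("trapezoidal integration reproduces closed-form areas", {
  # rectangle pulse: area = h * w
  tt <- seq(0, 1, by = 0.001)
  rect <- ifelse(tt >= 0.4 & tt <= 0.6, 5, 0)
  area <- integrate_peak(chrom_from(tt, rect),
                         list(start_time = 0.4, end_time = 0.6))
  expect_equal(area, 5 * 0.2, tolerance = 0.01)

  # triangle: area = h * w / 2
  tri <- pmax(0, 3 * (1 - abs(tt - 0.5) / 0.1))
  area_tri <- integrate_peak(chrom_from(tt, tri),
                             list(start_time = 0.4, end_time = 0.6))
  expect_equal(area_tri, 3 * 0.2 / 2, tolerance = 0.01)

  # dense Gaussian: area within 0.5 % of A (the closed-form integral)
  g <- gauss_trace(A = 5000, rt = 1, sigma = 0.02)
  area_g <- integrate_peak(g, list(start_time = 0.8, end_time = 1.2))
  expect_equal(area_g, 5000, tolerance = 5e-3)

  expect_error(integrate_peak(g, list(start_time = -1, end_time = 0.5)),
               class = "caffval_invalid_argument")
})

test_that("integration is additive over contiguous sub-intervals", {
  g <- gauss_trace(A = 5000, rt = 1, sigma = 0.02)
  whole <- integrate_peak(g, list(start_time = 0.8, end_time = 1.2))
  left <- integrate_peak(g, list(start_time = 0.8, end_time = 1.0))
  right <- integrate_peak(g, list(start_time = 1.0, end_time = 1.2))
  expect_equal(left + right, whole, tolerance = 1e-10)
})

test_that("measured area is invariant to a constant trace offset", {
  base <- gauss_trace(A = 5000, rt = 1, sigma = 0.02)
  shifted <- chrom_from(base$time_min, base$signal + 50)
  a0 <- measure_peak_area(base, 1, min_height = 100)$area
  a1 <- measure_peak_area(shifted, 1, min_height = 100)$area
  expect_equal(a1, a0, tolerance = 5e-3)
})

test_that("retention-time matching applies the nearest-then-larger-area rule", {
  pks <- tibble::tibble(apex_time = c(1.0), start_time = 0.9, end_time = 1.1,
                        height = 10, area = 5)
  expect_equal(match_analyte(pks, 1.0, 0.1)$apex_time, 1.0)
  expect_null(match_analyte(pks, 2.0, 0.1))
  expect_null(match_analyte(pks[0, ], 1.0, 0.1))

  # equidistant candidates: tie broken toward the larger area
  two <- tibble::tibble(apex_time = c(0.95, 1.05), start_time = c(0.9, 1.0),
                        end_time = c(1.0, 1.1), height = c(5, 5), area = c(2, 9))
  expect_equal(match_analyte(two, 1.0, 0.1)$area, 9)
  expect_error(match_analyte(two, 1.0, 0), class = "caffval_invalid_argument")
})

test_that("noise-free generator output integrates to its ground-truth area", {
  m0 <- response_model(slope = 50, injection_cv = 0, retention_time = 1)
  for (conc in c(10, 100, 1000)) {
    ch <- generate_chromatogram(conc, m0, noise_sd = 0, duration = 2)
    got <- measure_peak_area(ch, 1, min_height = 1)$area
    expect_equal(got, attr(ch, "true_area"), tolerance = 5e-3)
  }
})
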