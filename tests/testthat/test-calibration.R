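test_that("exact data give exact coefficients with zero standard errors", {
  x <- c(10, 50, 100, 250, 500, 1000)
  fit <- fit_calibration(tibble::tibble(conc_mg_L = x, response = 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(fit$se_slope, 1e-10)
  expect_lt(fit$se_intercept, 1e-8)

  flat <- fit_calibration(tibble::tibble(conc_mg_L = x, response = rep(7, 6)))
  expect_equal(flat$slope, 0)

  expect_error(
    fit_calibration(tibble::tibble(conc_mg_L = rep(5, 6), response = 1:6)),
    class = "caffval_degenerate_design")
})

test_that("OLS standard errors match the textbook closed forms", {
  set.seed(21)
  x <- c(10, 50, 100, 250, 500, 1000)
  y <- 50 * x + rnorm(6, 0, 300)
  fit <- fit_calibration(tibble::tibble(conc_mg_L = x, response = y))

  # independent oracle: direct evaluation of the unweighted-OLS formulas
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  s <- sqrt(sum((y - a - b * x)^2) / (n - 2))
  expect_equal(fit$slope, b)
  expect_equal(fit$intercept, a)
  expect_equal(fit$residual_sd, s)
  expect_equal(fit$se_slope, s / sqrt(sxx))
  expect_equal(fit$se_intercept, s * sqrt(1 / n + mean(x)^2 / sxx))
})

test_that("LOD and LOQ follow the 3.3x / 10x intercept-SE definition", {
  fit <- make_fit(slope = 2, se_intercept = 2)
  expect_equal(lod(fit), 3.3)
  expect_equal(loq(fit), 10)
  expect_equal(lod(make_fit(slope = 5, se_intercept = 0)), 0)

  # the LOQ/LOD ratio is 10/3.3 for any fit with positive SE
  set.seed(9)
  for (i in 1:5) {
    f <- make_fit(slope = runif(1, 1, 100), se_intercept = runif(1, 0.1, 10))
    expect_equal(loq(f) / lod(f), 10 / 3.3)
  }
  expect_error(lod(make_fit(slope = -1, se_intercept = 1)),
               class = "caffval_invalid_fit")
})

test_that("slope comparison computes the two-line t-test", {
  fa <- make_fit(slope = 2, se_slope = 0.1)
  fb <- make_fit(slope = 3, se_slope = 0.1)
  res <- compare_slopes(fa, fb)
  expect_equal(res$t_statistic, -1 / sqrt(0.02))
  expect_equal(res$df, 8)
  expect_true(res$matrix_effect)

  # identical fits: t = 0, no matrix effect (perfect-fit SE floor warns)
  expect_no_warning(same <- compare_slopes(fa, fa, df_method = "classical"))
  expect_equal(same$t_statistic, 0)
  expect_false(same$matrix_effect)

  # symmetry: swapping arguments flips the sign, keeps the p-value
  swapped <- compare_slopes(fb, fa)
  expect_equal(swapped$t_statistic, -res$t_statistic)
  expect_equal(swapped$p_value, res$p_value)

  # zero-SE fits fall back to a numerical floor with a warning
  pa <- make_fit(slope = 2, se_slope = 0)
  expect_warning(z <- compare_slopes(pa, pa))
  expect_equal(z$t_statistic, 0)
})

test_that("inverse prediction recovers concentration and its uncertainty", {
  x <- c(10, 50, 100, 250, 500, 1000)
  fit <- fit_calibration(tibble::tibble(conc_mg_L = x, response = 2 * x + 1))
  # response 1 inverts to conc 0, below the calibrated range: warns and flags
  expect_warning(q0 <- quantify(fit, 1), "extrapolated")
  expect_equal(q0$conc_mg_L, 0)
  expect_true(q0$extrapolated)
  expect_equal(quantify(fit, 201)$conc_mg_L, 100)

  # s_x0 matches the standard formula on a noisy fit
  set.seed(3)
  y <- 2 * x + rnorm(6, 0, 5)
  nf <- fit_calibration(tibble::tibble(conc_mg_L = x, response = y))
  q <- quantify(nf, 300, m_replicates = 2)
  conc <- (300 - nf$intercept) / nf$slope
  expect_equal(q$s_x0_mg_L,
               (nf$residual_sd / nf$slope) *
                 sqrt(1 / 2 + 1 / 6 + (conc - mean(x))^2 / sum((x - mean(x))^2)))

  # extrapolation beyond the calibrated range flags, not fails
  expect_warning(ex <- quantify(fit, 2 * 1500 + 1))
  expect_true(ex$extrapolated)
  expect_error(quantify(make_fit(2, mode = "standard_addition"), 10),
               class = "caffval_invalid_argument")
})

test_that("quantification inverts the response model for any concentration", {
  m0 <- response_model(slope = 50, intercept = 25, injection_cv = 0)
  cal <- generate_calibration_set(model = m0, seed = 1)
  fit <- fit_calibration(cal)
  for (conc in c(15, 100, 750)) {
    expect_equal(quantify(fit, 50 * conc + 25)$conc_mg_L, conc)
  }
})

test_that("tidy and glance expose the fit in broom style", {
  cal <- generate_calibration_set(seed = 2)
  fit <- fit_calibration(cal)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$lod_mg_L, lod(fit))
  expect_equal(gl$nobs, 6)
})
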