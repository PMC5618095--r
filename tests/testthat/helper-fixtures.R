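# Shared fixtures: built in code, no files.

# A calibration_fit with prescribed coefficients, for formula-level checks.
make_fit <- function(slope, intercept = 0, se_slope = 0, se_intercept = 0,
                     residual_sd = 0, n_points = 6, mode = "external",
                     mean_conc = 318.3333, sxx = 684833.3,
                     conc_range = c(10, 1000)) {
  structure(
    list(slope = slope, intercept = intercept, se_slope = se_slope,
         se_intercept = se_intercept, residual_sd = residual_sd,
         n_points = n_points, r_squared = 1, mode = mode, weighting = "none",
         mean_conc = mean_conc, sxx = sxx, conc_range = conc_range,
         response_range = slope * conc_range + intercept, lm = NULL),
    class = "calibration_fit"
  )
}

# A chromatogram from explicit time/signal vectors.
chrom_from <- function(time_min, signal) {
  as_chromatogram(tibble::tibble(time_min = time_min, signal = signal))
}

# Dense Gaussian trace: area A, apex rt, width sigma, on optional baseline.
gauss_trace <- function(A = 5000, rt = 1, sigma = 0.02, dt = 1 / 1500,
                        t_max = 2, baseline = 0) {
  tt <- seq(0, t_max, by = dt)
  chrom_from(tt, A * exp(-(tt - rt)^2 / (2 * sigma^2)) /
               (sigma * sqrt(2 * pi)) + baseline)
}

# Study design matching the reference fortification conditions but with
# overridable pieces, used across precision/recovery tests.
ref_design <- function(...) {
  args <- list(...)
  do.call(study_design, args)
}
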