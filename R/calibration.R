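#' Fit a calibration line
#'
#' Ordinary least squares of detector response on concentration, for either
#' an external-standard or a standard-addition series. Parameter standard
#' errors come from the usual unweighted-OLS formulas with n - 2 residual
#' degrees of freedom. A weighted (1/conc) fit is available but off by
#' default.
#'
#' @param data Data frame with a concentration column and a response column.
#' @param conc,response Column names (strings) holding concentration (mg/L)
#'   and detector response; defaults `"conc_mg_L"`, `"response"`.
#' @param mode `"external"` or `"standard_addition"` (bookkeeping; the fit is
#'   identical).
#' @param weighting `"none"` (default) or `"1/x"`.
#'
#' @return A `calibration_fit` with fields `slope`, `intercept`, `se_slope`,
#'   `se_intercept`, `residual_sd`, `n_points`, `r_squared`, `mode`, plus the
#'   design summaries (`mean_conc`, `sxx`, `conc_range`, `response_range`)
#'   needed for inverse prediction.
#' @examples
#' cal <- generate_calibration_set(seed = 1)
#' fit_calibration(cal)
#' @export
fit_calibration <- function(data, conc = "conc_mg_L", response = "response",
                            mode = c("external", "standard_addition"),
                            weighting = c("none", "1/x")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  x <- data[[conc]]
  y <- data[[response]]
  if (is.null(x) || is.null(y)) {
    abort("Calibration data must contain the concentration and response columns.",
          class = "caffval_invalid_argument")
  }
  if (length(unique(x)) < 3) {
    abort("Need at least 3 distinct concentration levels.",
          class = "caffval_degenerate_design")
  }
  w <- if (weighting == "1/x") 1 / x else NULL
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  # noise-free series are legitimate here; silence the perfect-fit notice
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- sm$coefficients
  structure(
    list(
      slope = unname(cf["x", "Estimate"]),
      intercept = unname(cf["(Intercept)", "Estimate"]),
      se_slope = unname(cf["x", "Std. Error"]),
      se_intercept = unname(cf["(Intercept)", "Std. Error"]),
      residual_sd = sm$sigma,
      n_points = length(x),
      r_squared = sm$r.squared,
      mode = mode,
      weighting = weighting,
      mean_conc = mean(x),
      sxx = sum((x - mean(x))^2),
      conc_range = range(x),
      response_range = range(fitted(fit)),
      lm = fit
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s, weighting: %s)\n", x$mode, x$weighting))
  cat(sprintf("  slope     %.6g (SE %.3g)\n", x$slope, x$se_slope))
  cat(sprintf("  intercept %.6g (SE %.3g)\n", x$intercept, x$se_intercept))
  cat(sprintf("  residual SD %.4g on %d points, R^2 = %.5f\n",
              x$residual_sd, x$n_points, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One row per coefficient with estimate and standard error.
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' Glance at a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit summaries including LOD/LOQ in mg/L.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sigma = x$residual_sd, nobs = x$n_points,
    lod_mg_L = lod(x), loq_mg_L = loq(x)
  )
}

#' Limits of detection and quantification from a calibration fit
#'
#' LOD = 3.3 · SE(intercept) / slope; LOQ = 10 · SE(intercept) / slope,
#' both in the concentration units of the calibration (mg/L here). Their
#' ratio is therefore always 10/3.3.
#'
#' @param fit A `calibration_fit` with positive slope.
#' @return Concentration in mg/L.
#' @examples
#' cal <- generate_calibration_set(seed = 1)
#' fit <- fit_calibration(cal)
#' c(lod(fit), loq(fit))
#' @export
lod <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) {
    abort("LOD requires a positive calibration slope.",
          class = "caffval_invalid_fit")
  }
  3.3 * fit$se_intercept / fit$slope
}

#' @rdname lod
#' @export
loq <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) {
    abort("LOQ requires a positive calibration slope.",
          class = "caffval_invalid_fit")
  }
  10 * fit$se_intercept / fit$slope
}

#' Compare two calibration slopes (matrix-effect t-test)
#'
#' Tests equality of the external-standard and standard-addition slopes with
#' `t = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`. Degrees of freedom are the
#' classical `n_a + n_b - 4` by default, or Welch–Satterthwaite. A
#' significant difference indicates a matrix effect.
#'
#' @param fit_a,fit_b `calibration_fit` objects.
#' @param alpha Two-sided significance level (default 0.05).
#' @param df_method `"classical"` or `"welch"`.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `matrix_effect`.
#' @examples
#' cal <- generate_calibration_set(seed = 1)
#' f <- fit_calibration(cal)
#' compare_slopes(f, f)
#' @export
compare_slopes <- function(fit_a, fit_b, alpha = 0.05,
                           df_method = c("classical", "welch")) {
  df_method <- match.arg(df_method)
  se2 <- fit_a$se_slope^2 + fit_b$se_slope^2
  if (se2 == 0) {
    # perfect fits: fall back to a floor scaled to the slopes so a genuine
    # difference still registers and identical slopes give t = 0
    floor_se <- .Machine$double.eps * max(abs(fit_a$slope), abs(fit_b$slope), 1)
    se2 <- floor_se^2
    warn("Both slope SEs are zero (perfect fits); t computed with a numerical floor.")
  }
  t_stat <- (fit_a$slope - fit_b$slope) / sqrt(se2)
  df <- if (df_method == "classical") {
    fit_a$n_points + fit_b$n_points - 4
  } else {
    se2^2 / (fit_a$se_slope^4 / (fit_a$n_points - 2) +
               fit_b$se_slope^4 / (fit_b$n_points - 2))
  }
  p <- 2 * pt(-abs(t_stat), df)
  tibble::tibble(t_statistic = t_stat, df = df, p_value = p,
                 matrix_effect = p < alpha)
}

#' Quantify an unknown by inverse prediction
#'
#' `conc = (response - intercept) / slope`, with the standard
#' inverse-prediction standard deviation
#' `s_x0 = (residual_sd / slope) * sqrt(1/m + 1/n + (conc - mean_conc)^2 / Sxx)`
#' where `m` is the number of replicate measurements averaged into
#' `response`. Responses outside the calibrated range are flagged as
#' extrapolated (with a warning) but still quantified.
#'
#' @param fit An external-mode `calibration_fit`.
#' @param response Detector response(s), signal·min.
#' @param m_replicates Replicates averaged into each response (default 1).
#' @return Tibble with `response`, `conc_mg_L`, `s_x0_mg_L`, `extrapolated`.
#' @examples
#' cal <- generate_calibration_set(seed = 1)
#' fit <- fit_calibration(cal)
#' quantify(fit, 5000)
#' @export
quantify <- function(fit, response, m_replicates = 1) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$mode != "external") {
    abort("Quantification requires an external calibration fit.",
          class = "caffval_invalid_argument")
  }
  conc <- (response - fit$intercept) / fit$slope
  s_x0 <- (fit$residual_sd / abs(fit$slope)) *
    sqrt(1 / m_replicates + 1 / fit$n_points +
           (conc - fit$mean_conc)^2 / fit$sxx)
  extrap <- conc < fit$conc_range[1] | conc > fit$conc_range[2]
  if (any(extrap)) {
    warn(sprintf("%d response(s) outside the calibrated range %g-%g mg/L; flagged as extrapolated.",
                 sum(extrap), fit$conc_range[1], fit$conc_range[2]))
  }
  tibble::tibble(response = response, conc_mg_L = conc, s_x0_mg_L = s_x0,
                 extrapolated = extrap)
}

#' Plot a calibration fit with its data
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  df <- tibble::tibble(conc_mg_L = object$lm$model$x,
                       response = object$lm$model$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_mg_L, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Concentration (mg/L)", y = "Peak area (signal·min)") +
    ggplot2::theme_minimal()
}
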