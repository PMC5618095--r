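#' Relative standard uncertainty of the sample mass
#'
#' Balance tolerances are treated as rectangular distributions, so the
#' standard uncertainty is tolerance/sqrt(3), expressed relative to the
#' weighed mass in percent.
#'
#' @param balance_tolerance Balance tolerance, g (>= 0).
#' @param sample_mass Weighed mass, g (> 0).
#' @return Relative standard uncertainty, %.
#' @examples
#' u_mass(0.0005, 0.5)
#' @export
u_mass <- function(balance_tolerance, sample_mass) {
  assert_scalar_number(balance_tolerance, "balance_tolerance", lower = 0)
  assert_scalar_number(sample_mass, "sample_mass", lower = 0, strict_lower = TRUE)
  100 * (balance_tolerance / sqrt(3)) / sample_mass
}

#' Relative standard uncertainty of the dilution volume
#'
#' Root-sum-of-squares of a rectangular glassware-tolerance term and a
#' rectangular thermal-expansion term `volume * temp_coefficient * temp_range`,
#' relative to the nominal volume in percent.
#'
#' @param glassware_tolerance Glassware tolerance, mL (>= 0).
#' @param volume Nominal volume, mL (> 0).
#' @param temp_coefficient Volumetric expansion coefficient per degree C
#'   (default 2.1e-4, water).
#' @param temp_range Half-width of the laboratory temperature excursion,
#'   degrees C (default 0: no thermal term).
#' @return Relative standard uncertainty, %.
#' @examples
#' u_volume(0.02, 10)
#' @export
u_volume <- function(glassware_tolerance, volume, temp_coefficient = 2.1e-4,
                     temp_range = 0) {
  assert_scalar_number(glassware_tolerance, "glassware_tolerance", lower = 0)
  assert_scalar_number(volume, "volume", lower = 0, strict_lower = TRUE)
  u_glass <- glassware_tolerance / sqrt(3)
  u_temp <- volume * temp_coefficient * temp_range / sqrt(3)
  100 * sqrt(u_glass^2 + u_temp^2) / volume
}

#' Relative standard uncertainty of the calibration step
#'
#' The inverse-prediction standard deviation `s_x0` at the working
#' concentration, relative to that concentration in percent.
#'
#' @param fit A `calibration_fit`.
#' @param conc Working concentration, mg/L (> 0).
#' @param m_replicates Replicate measurements averaged per sample.
#' @return Relative standard uncertainty, %.
#' @export
u_calibration <- function(fit, conc, m_replicates = 1) {
  assert_scalar_number(conc, "conc", lower = 0, strict_lower = TRUE)
  response <- fit$slope * conc + fit$intercept
  q <- suppressWarnings(quantify(fit, response, m_replicates))
  100 * q$s_x0_mg_L / conc
}

#' Relative standard uncertainty from method bias (recovery)
#'
#' Default variant combines the bias magnitude with the standard error of its
#' estimate: `sqrt((100 - mean_recovery)^2 + (sd_recovery/sqrt(n))^2)`.
#' Alternatives: `"se_only"` uses only the recovery standard error (bias
#' assumed corrected), `"rectangular"` treats the bias as a rectangular
#' half-width (`|bias|/sqrt(3)` RSS'd with the SE).
#'
#' @param rec A one-row recovery result from [recovery()] (or a list with
#'   `mean_recovery`, `sd_recovery`, `n`).
#' @param variant `"bias_and_se"` (default), `"se_only"`, or `"rectangular"`.
#' @return Relative standard uncertainty, %.
#' @examples
#' u_bias(list(mean_recovery = 96.7, sd_recovery = 3.3, n = 6))
#' @export
u_bias <- function(rec, variant = c("bias_and_se", "se_only", "rectangular")) {
  variant <- match.arg(variant)
  bias <- 100 - rec$mean_recovery
  se <- rec$sd_recovery / sqrt(rec$n)
  switch(variant,
    bias_and_se = sqrt(bias^2 + se^2),
    se_only = se,
    rectangular = sqrt(bias^2 / 3 + se^2)
  )
}

#' Relative standard uncertainty from method precision
#'
#' The reproducibility RSD enters the budget unchanged as a relative
#' standard uncertainty.
#'
#' @param prec A one-row precision result from [precision_summary()] (or a
#'   list with `rsd_R`).
#' @return Relative standard uncertainty, % (equals `rsd_R`).
#' @export
u_precision <- function(prec) {
  if (is.null(prec$rsd_R) || is.na(prec$rsd_R)) {
    abort("Reproducibility RSD is undefined; run a multi-day study.",
          class = "caffval_invalid_argument")
  }
  prec$rsd_R
}

#' Combine relative uncertainty components into a budget
#'
#' The combined standard uncertainty is the root-sum-of-squares of the named
#' components (assumed independent); the expanded uncertainty is `k` times
#' that (k = 2 for approximately 95 % confidence). Each component's share of
#' the squared budget is reported.
#'
#' @param components Named numeric vector or list of relative standard
#'   uncertainties in percent (all >= 0). Conventional names: `mass`,
#'   `volume`, `calibration`, `bias`, `precision`, optionally `stock_standard`.
#' @param k Coverage factor (> 0, default 2).
#' @return An `uncertainty_budget`: list with `components` (tibble of value
#'   and share), `combined`, `coverage_factor`, `expanded`.
#' @examples
#' combine_uncertainty(c(a = 3, b = 4))
#' @export
combine_uncertainty <- function(components, k = 2) {
  comp <- unlist(components)
  if (is.null(names(comp)) || any(names(comp) == "")) {
    abort("All components must be named.", class = "caffval_invalid_argument")
  }
  if (any(comp < 0)) {
    abort("Components must be non-negative.", class = "caffval_invalid_argument")
  }
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  combined <- sqrt(sum(comp^2))
  share <- if (combined > 0) comp^2 / combined^2 else rep(0, length(comp))
  structure(
    list(
      components = tibble::tibble(component = names(comp), u_percent = unname(comp),
                                  share = unname(share)),
      combined = combined,
      coverage_factor = k,
      expanded = k * combined
    ),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Uncertainty budget (relative, %)\n")
  print(as.data.frame(x$components), row.names = FALSE)
  cat(sprintf("  combined u_c = %.4g %%; expanded U = %.4g %% (k = %g)\n",
              x$combined, x$expanded, x$coverage_factor))
  mv <- x$components$share[x$components$component %in% c("mass", "volume")]
  if (length(mv) && sum(mv) < 0.01) {
    cat("  note: mass and volume contribute < 1% of the budget.\n")
  }
  invisible(x)
}

#' Tidy an uncertainty budget
#'
#' @param x An `uncertainty_budget`.
#' @param ... Unused.
#' @return The component tibble with the combined and expanded rows appended.
#' @export
tidy.uncertainty_budget <- function(x, ...) {
  dplyr::bind_rows(
    x$components,
    tibble::tibble(component = c("combined", "expanded"),
                   u_percent = c(x$combined, x$expanded),
                   share = c(NA_real_, NA_real_))
  )
}
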