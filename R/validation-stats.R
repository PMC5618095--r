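#' Intra- and inter-day precision at one fortification level
#'
#' Separates repeatability (within-day) and reproducibility (within +
#' between-day) variation by one-way ANOVA with day as the factor:
#' `RSDr = 100 * sqrt(MS_within) / grand mean`, and
#' `RSD_R = 100 * sqrt(MS_within + s2_between) / grand mean` with the
#' between-day variance component `(MS_between - MS_within) / n_per_day`
#' truncated at zero. HORRAT ratios are attached using the total analyte
#' content (background + spike) as the Horwitz concentration by default.
#'
#' @param study A `validation_study` (or a data frame with columns
#'   `spike_pct`, `day`, `measured_pct`).
#' @param level Spike level (%w/w) to summarise.
#' @param background Background content (%w/w) used to form the total
#'   content for the Horwitz concentration; defaults to the study design's.
#' @param horwitz_basis `"total"` (default) or `"spike"`: concentration basis
#'   for the Horwitz predicted RSD.
#' @return One-row tibble (`level`, `rsd_r`, `rsd_R`, `horrat_r`, `horrat_R`,
#'   `n_within`, `n_days`, `acceptable`). `rsd_R` and `horrat_R` are `NA`
#'   (with a warning) for single-day data; `acceptable` requires both HORRAT
#'   values below 2.
#' @examples
#' st <- generate_validation_study(study_design(seed = 3))
#' precision_summary(st, 0.5)
#' @export
precision_summary <- function(study, level, background = NULL,
                              horwitz_basis = c("total", "spike")) {
  horwitz_basis <- match.arg(horwitz_basis)
  design <- attr(study, "design")
  background <- background %||% design$background_content
  if (is.null(background)) {
    abort("Supply `background` when the study carries no design metadata.",
          class = "caffval_invalid_argument")
  }
  d <- dplyr::filter(study, .data$spike_pct == level)
  if (nrow(d) < 2) {
    abort("Need at least 2 measurements at this level.",
          class = "caffval_invalid_argument")
  }
  grand <- mean(d$measured_pct)
  n_days <- length(unique(d$day))
  if (n_days >= 2) {
    av <- withCallingHandlers(
      anova(aov(measured_pct ~ factor(day), data = d)),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    ms_within <- av["Residuals", "Mean Sq"]
    ms_between <- av["factor(day)", "Mean Sq"]
    n_per <- nrow(d) / n_days # balanced designs; harmonic mean otherwise
    s2_between <- max((ms_between - ms_within) / n_per, 0)
  } else {
    warn("Single-day data: reproducibility RSD is undefined.")
    ms_within <- var(d$measured_pct)
    s2_between <- NA_real_
  }
  rsd_r <- 100 * sqrt(ms_within) / grand
  rsd_R <- if (n_days >= 2) 100 * sqrt(ms_within + s2_between) / grand else NA_real_
  c_frac <- if (horwitz_basis == "total") (background + level) / 100 else level / 100
  h_r <- horrat(rsd_r, c_frac, basis = "repeatability")
  h_R <- if (!is.na(rsd_R)) horrat(rsd_R, c_frac, basis = "reproducibility") else
    tibble::tibble(horrat_value = NA_real_, pass = NA)
  tibble::tibble(
    level = level, rsd_r = rsd_r, rsd_R = rsd_R,
    horrat_r = h_r$horrat_value, horrat_R = h_R$horrat_value,
    n_within = as.integer(nrow(d) / n_days), n_days = as.integer(n_days),
    acceptable = isTRUE(h_r$pass) && isTRUE(h_R$pass)
  )
}

#' Horwitz predicted relative standard deviation
#'
#' The Horwitz function predicts the reproducibility RSD expected of a
#' well-behaved method at analyte mass fraction `c`:
#' `PRSD_R = 2^(1 - 0.5 * log10(c))` percent. Repeatability is predicted via
#' the empirical rule r = 0.66 R, i.e. `PRSD_r = 0.66 * PRSD_R`.
#'
#' @param c_frac Analyte mass fraction, in (0, 1].
#' @param basis `"reproducibility"` (default) or `"repeatability"`.
#' @return Predicted RSD in percent.
#' @examples
#' horwitz_prsd(0.01) # 4 %
#' @export
horwitz_prsd <- function(c_frac, basis = c("reproducibility", "repeatability")) {
  basis <- match.arg(basis)
  if (any(c_frac <= 0) || any(c_frac > 1)) {
    abort("`c_frac` must be a mass fraction in (0, 1].",
          class = "caffval_invalid_argument")
  }
  prsd <- 2^(1 - 0.5 * log10(c_frac))
  if (basis == "repeatability") 0.66 * prsd else prsd
}

#' HORRAT ratio and its acceptance verdict
#'
#' The HORRAT is the observed RSD divided by the Horwitz prediction at the
#' same concentration; values strictly below 2 are acceptable.
#'
#' @param observed_rsd Observed RSD in percent (>= 0).
#' @param c_frac Analyte mass fraction in (0, 1].
#' @param basis Passed to [horwitz_prsd()].
#' @return Tibble with `horrat_value` and `pass` (strict `< 2`).
#' @examples
#' horrat(4.5, 0.018)
#' @export
horrat <- function(observed_rsd, c_frac,
                   basis = c("reproducibility", "repeatability")) {
  if (any(observed_rsd < 0)) {
    abort("`observed_rsd` must be non-negative.",
          class = "caffval_invalid_argument")
  }
  ratio <- observed_rsd / horwitz_prsd(c_frac, basis)
  tibble::tibble(horrat_value = ratio, pass = ratio < 2)
}

#' Spike recovery at one fortification level
#'
#' Per-replicate recovery is `100 * (measured_total - background) / spike`;
#' the level passes when the mean lies within 80-120 % (the +/-20 % window
#' around the theoretical fortified content). The background defaults to the
#' mean of the study's unspiked (spike 0) replicates.
#'
#' @param study A `validation_study` or compatible data frame.
#' @param level Spike level, %w/w (> 0).
#' @param background Optional external background content, %w/w.
#' @return One-row tibble: `level`, `mean_recovery`, `sd_recovery`, `n`,
#'   `acceptable`.
#' @examples
#' st <- generate_validation_study(study_design(seed = 3))
#' recovery(st, 1.0)
#' @export
recovery <- function(study, level, background = NULL) {
  if (level <= 0) {
    abort("`level` (the spike) must be positive.",
          class = "caffval_invalid_argument")
  }
  if (is.null(background)) {
    blanks <- dplyr::filter(study, .data$spike_pct == 0)
    if (nrow(blanks) == 0) {
      abort("No unspiked replicates in the study; supply `background`.",
            class = "caffval_invalid_argument")
    }
    background <- mean(blanks$measured_pct)
  }
  d <- dplyr::filter(study, .data$spike_pct == level)
  if (nrow(d) < 2) {
    abort("Need at least 2 fortified measurements.",
          class = "caffval_invalid_argument")
  }
  rec <- 100 * (d$measured_pct - background) / level
  tibble::tibble(
    level = level, mean_recovery = mean(rec), sd_recovery = sd(rec),
    n = as.integer(nrow(d)),
    acceptable = mean(rec) >= 80 && mean(rec) <= 120
  )
}
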