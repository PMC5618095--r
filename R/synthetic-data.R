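#' Detector response model for the simulated GC-FID system
#'
#' Describes how integrated peak area responds to injected caffeine
#' concentration: a straight line `area = slope * conc + intercept` with a
#' multiplicative injection error of relative standard deviation
#' `injection_cv`, and a Gaussian peak shape at a fixed retention time.
#'
#' @param slope Detector response (area units) per mg/L. Must be positive.
#' @param intercept Detector response at zero concentration.
#' @param injection_cv Relative standard deviation of the injected response
#'   (unitless, e.g. 0.02 for 2 %). Must be non-negative.
#' @param retention_time Analyte retention time in minutes.
#' @param peak_sigma Gaussian peak standard deviation in minutes.
#'
#' @return An object of class `response_model` (a named list).
#' @examples
#' response_model(slope = 50)
#' @export
response_model <- function(slope = 50, intercept = 0, injection_cv = 0.02,
                           retention_time = 7.5, peak_sigma = 0.02) {
  assert_scalar_number(slope, "slope", lower = 0, strict_lower = TRUE)
  assert_scalar_number(intercept, "intercept")
  assert_scalar_number(injection_cv, "injection_cv", lower = 0)
  assert_scalar_number(retention_time, "retention_time", lower = 0, strict_lower = TRUE)
  assert_scalar_number(peak_sigma, "peak_sigma", lower = 0, strict_lower = TRUE)
  structure(
    list(slope = slope, intercept = intercept, injection_cv = injection_cv,
         retention_time = retention_time, peak_sigma = peak_sigma),
    class = "response_model"
  )
}

#' Fortification study design
#'
#' Encodes the validation-study layout: a coffee matrix with a known
#' background caffeine content is spiked at several levels (percent w/w,
#' relative amounts added on top of the background), each measured in
#' replicate on several days. Per-level true recoveries and within-/
#' between-day coefficients of variation define the generative truth.
#'
#' `within_day_cv` and `between_day_cv` may be scalars (recycled) or one
#' value per spike level. Defaults reproduce a study with repeatability RSDs
#' of 4.1/2.5/2.0 % and reproducibility RSDs of 4.5/3.4/2.2 % at spikes of
#' 0.5/1.0/2.0 %w/w over a 1.3 %w/w background, with true recoveries
#' 93.5/96.7/102.0 % (the between-day CVs are sqrt(RSD_R^2 - RSDr^2)).
#'
#' @param background_content Background caffeine content, %w/w.
#' @param spike_levels Spike amounts, %w/w, all positive.
#' @param days Number of days (>= 1).
#' @param replicates_per_day Replicates within each day (>= 2).
#' @param true_recovery_per_level True recovery fractions in (0, 2), one per
#'   level (scalar recycled).
#' @param within_day_cv Within-day (repeatability) CV, unitless.
#' @param between_day_cv Between-day CV, unitless.
#' @param n_blanks Number of unspiked replicates included so downstream
#'   recovery estimation can measure the background in-study.
#' @param seed Integer seed making the generated study reproducible.
#'
#' @return An object of class `study_design`.
#' @examples
#' study_design()
#' @export
study_design <- function(background_content = 1.3,
                         spike_levels = c(0.5, 1.0, 2.0),
                         days = 2,
                         replicates_per_day = 3,
                         true_recovery_per_level = c(0.935, 0.967, 1.020),
                         within_day_cv = c(0.041, 0.025, 0.020),
                         between_day_cv = c(0.018547, 0.023043, 0.0091652),
                         n_blanks = 6,
                         seed = 1L) {
  assert_scalar_number(background_content, "background_content", lower = 0)
  if (!length(spike_levels) || any(spike_levels <= 0)) {
    abort("`spike_levels` must all be positive.", class = "caffval_invalid_argument")
  }
  assert_scalar_number(days, "days", lower = 1)
  assert_scalar_number(replicates_per_day, "replicates_per_day", lower = 2)
  nl <- length(spike_levels)
  rec <- rep_len(true_recovery_per_level, nl)
  wcv <- rep_len(within_day_cv, nl)
  bcv <- rep_len(between_day_cv, nl)
  if (any(rec <= 0 | rec >= 2)) {
    abort("`true_recovery_per_level` must lie in (0, 2).",
          class = "caffval_invalid_argument")
  }
  if (any(wcv < 0) || any(bcv < 0)) {
    abort("CVs must be non-negative.", class = "caffval_invalid_argument")
  }
  structure(
    list(background_content = background_content, spike_levels = spike_levels,
         days = as.integer(days), replicates_per_day = as.integer(replicates_per_day),
         true_recovery_per_level = rec, within_day_cv = wcv,
         between_day_cv = bcv, n_blanks = as.integer(n_blanks),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Simulate a chromatogram for one injection
#'
#' Produces a time/signal trace with a single Gaussian analyte peak whose
#' true area is `(slope * true_conc + intercept) * (1 + eps)`, with
#' `eps ~ Normal(0, injection_cv)`, on a baseline of white Gaussian noise.
#' The realised ground-truth area is attached so downstream integration can
#' be checked against it.
#'
#' @param true_conc True concentration of the injected extract, mg/L (>= 0).
#' @param model A [response_model()].
#' @param noise_sd Additive baseline noise standard deviation, signal units.
#' @param sampling_rate Sampling rate in Hz; must place at least 20 samples
#'   per `peak_sigma`.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param duration Trace length in minutes; defaults to the retention time
#'   plus one minute.
#'
#' @return A `chromatogram`: a tibble with columns `time_min`, `signal` and
#'   attributes `true_area` (realised peak area) and `model`.
#' @examples
#' chrom <- generate_chromatogram(100, response_model(injection_cv = 0), noise_sd = 0)
#' attr(chrom, "true_area")
#' @export
generate_chromatogram <- function(true_conc, model = response_model(),
                                  noise_sd = 0.5, sampling_rate = 25,
                                  seed = NULL, duration = NULL) {
  assert_scalar_number(true_conc, "true_conc", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number of Hz.",
          class = "caffval_invalid_argument")
  }
  dt <- 1 / (sampling_rate * 60) # minutes between samples
  if (model$peak_sigma / dt < 20) {
    abort("`sampling_rate` too low: need >= 20 samples per peak_sigma.",
          class = "caffval_invalid_argument")
  }
  duration <- duration %||% (model$retention_time + 1)
  tt <- seq(0, duration, by = dt)
  with_seed(seed, {
    eps <- if (model$injection_cv > 0) rnorm(1, 0, model$injection_cv) else 0
    true_area <- (model$slope * true_conc + model$intercept) * (1 + eps)
    true_area <- max(true_area, 0)
    peak <- if (true_area > 0) {
      true_area * exp(-(tt - model$retention_time)^2 / (2 * model$peak_sigma^2)) /
        (model$peak_sigma * sqrt(2 * pi))
    } else {
      rep(0, length(tt))
    }
    noise <- if (noise_sd > 0) rnorm(length(tt), 0, noise_sd) else 0
    out <- tibble::tibble(time_min = tt, signal = peak + noise)
    attr(out, "true_area") <- true_area
    attr(out, "true_conc") <- true_conc
    attr(out, "model") <- model
    class(out) <- c("chromatogram", class(out))
    out
  })
}

#' Simulate an external calibration series
#'
#' Draws one detector response per concentration level from the response
#' model: `response = (slope * level + intercept) * (1 + eps)` with
#' `eps ~ Normal(0, injection_cv)` independently per level.
#'
#' @param levels Concentration levels, mg/L; at least 5 distinct values.
#' @param model A [response_model()].
#' @param seed Integer seed; fixed seed gives an identical table.
#' @param replicates Injections per level (default 1).
#'
#' @return A tibble with columns `conc_mg_L` and `response`.
#' @examples
#' generate_calibration_set(c(10, 50, 100, 250, 500, 1000), seed = 1)
#' @export
generate_calibration_set <- function(levels = c(10, 50, 100, 250, 500, 1000),
                                     model = response_model(), seed = 1L,
                                     replicates = 1L) {
  if (length(unique(levels)) < 5) {
    abort("Need at least 5 distinct calibration levels.",
          class = "caffval_degenerate_design")
  }
  conc <- rep(sort(levels), each = replicates)
  with_seed(seed, {
    eps <- if (model$injection_cv > 0) rnorm(length(conc), 0, model$injection_cv) else 0
    tibble::tibble(
      conc_mg_L = conc,
      response = (model$slope * conc + model$intercept) * (1 + eps)
    )
  })
}

#' Simulate a fortified validation study
#'
#' For each spike level l, day d and replicate r the measured total content is
#' `(background + recovery_l * spike_l) * (1 + delta_{l,d}) * (1 + eps_{l,d,r})`
#' with `delta ~ Normal(0, between_day_cv_l)` shared within a day and
#' `eps ~ Normal(0, within_day_cv_l)` independent per measurement; negative
#' draws are truncated at zero (content cannot be negative). Unspiked blank
#' replicates (spike 0) are generated the same way with the level-1 CVs so
#' the background can be estimated in-study.
#'
#' @param design A [study_design()].
#' @param prep A [prep_protocol()]; carried as metadata for unit conversion.
#' @param model A [response_model()]; carried as metadata.
#'
#' @return A `validation_study`: tibble with columns `spike_pct`, `day`,
#'   `replicate`, `measured_pct`, plus attributes `design`, `prep`, `truth`
#'   (a tibble of per-level true totals and recoveries).
#' @examples
#' st <- generate_validation_study(study_design(seed = 7))
#' dplyr::count(st, spike_pct)
#' @export
generate_validation_study <- function(design = study_design(),
                                      prep = prep_protocol(),
                                      model = response_model()) {
  stopifnot(inherits(design, "study_design"))
  nl <- length(design$spike_levels)
  with_seed(derive_seed(design$seed, "validation_study"), {
    rows <- purrr::map_dfr(seq_len(nl), function(i) {
      spike <- design$spike_levels[i]
      truth <- design$background_content +
        design$true_recovery_per_level[i] * spike
      delta <- rnorm(design$days, 0, design$between_day_cv[i])
      purrr::map_dfr(seq_len(design$days), function(d) {
        eps <- rnorm(design$replicates_per_day, 0, design$within_day_cv[i])
        tibble::tibble(
          spike_pct = spike,
          day = d,
          replicate = seq_len(design$replicates_per_day),
          measured_pct = pmax(truth * (1 + delta[d]) * (1 + eps), 0)
        )
      })
    })
    blanks <- if (design$n_blanks > 0) {
      eps <- rnorm(design$n_blanks, 0, design$within_day_cv[1])
      tibble::tibble(
        spike_pct = 0, day = 1L, replicate = seq_len(design$n_blanks),
        measured_pct = pmax(design$background_content * (1 + eps), 0)
      )
    } else {
      NULL
    }
    out <- dplyr::bind_rows(blanks, rows)
    attr(out, "design") <- design
    attr(out, "prep") <- prep
    attr(out, "truth") <- tibble::tibble(
      spike_pct = design$spike_levels,
      true_recovery = design$true_recovery_per_level,
      true_total_pct = design$background_content +
        design$true_recovery_per_level * design$spike_levels
    )
    class(out) <- c("validation_study", class(out))
    out
  })
}

#' Simulate an internal quality-control series
#'
#' Generates QC measurements of the control sample analysed after every
#' five analytical runs: `measured ~ true_mean * (1 + Normal(0, cv))`,
#' indexed by cumulative run number (5, 10, 15, ...). Optional injected
#' disturbances (a sustained mean shift or point outliers, in units of the
#' true SD) are recorded as ground truth.
#'
#' @param n_runs Number of QC measurements (>= 1).
#' @param true_mean True QC content, %w/w.
#' @param cv Relative standard deviation of a QC measurement.
#' @param outlier_spec Optional list with elements `at` (indices into the
#'   series) and `shift_sd` (shift applied at those points, in SD units).
#' @param seed Integer seed.
#' @param run_spacing Analytical runs between QC injections (default 5).
#'
#' @return A tibble with columns `qc_index`, `run_index`, `measured_pct`,
#'   `shifted` (logical ground truth).
#' @examples
#' generate_qc_series(20, true_mean = 2.3, cv = 0.03, seed = 1)
#' @export
generate_qc_series <- function(n_runs, true_mean, cv, outlier_spec = NULL,
                               seed = 1L, run_spacing = 5L) {
  assert_scalar_number(n_runs, "n_runs", lower = 1)
  assert_scalar_number(true_mean, "true_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_number(cv, "cv", lower = 0)
  n_runs <- as.integer(n_runs)
  with_seed(derive_seed(seed, "qc_series"), {
    x <- true_mean * (1 + rnorm(n_runs, 0, cv))
    shifted <- rep(FALSE, n_runs)
    if (!is.null(outlier_spec)) {
      at <- as.integer(outlier_spec$at)
      stopifnot(all(at >= 1 & at <= n_runs))
      x[at] <- x[at] + outlier_spec$shift_sd * true_mean * cv
      shifted[at] <- TRUE
    }
    tibble::tibble(
      qc_index = seq_len(n_runs),
      run_index = run_spacing * seq_len(n_runs),
      measured_pct = pmax(x, 0),
      shifted = shifted
    )
  })
}

#' Write a chromatogram to the two-column CSV dialect
#'
#' @param chrom A `chromatogram`.
#' @param path Output CSV path (columns `time_min`, `signal`).
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(as.data.frame(chrom[c("time_min", "signal")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a chromatogram from the two-column CSV dialect
#'
#' @param path CSV with columns `time_min` and `signal`.
#' @return A `chromatogram` tibble.
#' @export
read_chromatogram_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "signal") %in% names(df))) {
    abort("Chromatogram CSV must have columns `time_min` and `signal`.",
          class = "caffval_invalid_argument")
  }
  as_chromatogram(tibble::as_tibble(df[c("time_min", "signal")]))
}
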