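#' Assemble a run configuration
#'
#' One self-contained configuration drives the whole validation study:
#' synthetic-data generation, calibration, precision/recovery, QC charting,
#' the uncertainty budget and the intake scenario. Sections are stored as
#' plain argument lists so the configuration serialises losslessly to JSON.
#'
#' @param seed Global integer seed; every stage derives its own substream.
#' @param prep Arguments for [prep_protocol()].
#' @param model Arguments for [response_model()].
#' @param design Arguments for [study_design()] (its `seed` is derived from
#'   the global seed).
#' @param calibration_levels External calibration levels, mg/L.
#' @param matrix_slope_factor Ratio of the standard-addition slope to the
#'   external slope (1 = no matrix effect).
#' @param qc List: `n_baseline`, `n_monitor`, `cv`, `spike_pct` (which spike
#'   level defines the QC sample; default 1.0 %w/w).
#' @param uncertainty List: `balance_tolerance` (g), `glassware_tolerance`
#'   (mL), `temp_coefficient`, `temp_range`, `k`, `u_bias_variant`,
#'   `stock_standard` (optional sixth component, %; default 0).
#' @param intake Arguments for [intake_scenario()].
#' @param simulate_traces If `TRUE`, calibration responses are obtained by
#'   generating and integrating full chromatograms rather than drawing areas
#'   directly (slower; exercises the signal-processing path).
#' @param noise_sd Baseline noise SD used when `simulate_traces = TRUE`.
#' @return A `run_config` list.
#' @examples
#' cfg <- run_config(seed = 1)
#' @export
run_config <- function(seed = 1L,
                       prep = list(),
                       model = list(),
                       design = list(),
                       calibration_levels = c(10, 50, 100, 250, 500, 1000),
                       matrix_slope_factor = 1,
                       qc = list(n_baseline = 20, n_monitor = 20, cv = 0.034,
                                 spike_pct = 1.0),
                       uncertainty = list(balance_tolerance = 0.0005,
                                          glassware_tolerance = 0.02,
                                          temp_coefficient = 2.1e-4,
                                          temp_range = 4, k = 2,
                                          u_bias_variant = "bias_and_se",
                                          stock_standard = 0),
                       intake = list(),
                       simulate_traces = FALSE,
                       noise_sd = 0.5) {
  cfg <- list(
    seed = as.integer(seed), prep = prep, model = model, design = design,
    calibration_levels = calibration_levels,
    matrix_slope_factor = matrix_slope_factor,
    qc = utils::modifyList(list(n_baseline = 20, n_monitor = 20, cv = 0.034,
                                spike_pct = 1.0), qc),
    uncertainty = utils::modifyList(
      list(balance_tolerance = 0.0005, glassware_tolerance = 0.02,
           temp_coefficient = 2.1e-4, temp_range = 4, k = 2,
           u_bias_variant = "bias_and_se", stock_standard = 0), uncertainty),
    intake = intake,
    simulate_traces = isTRUE(simulate_traces),
    noise_sd = noise_sd
  )
  # fail fast on inconsistent sections
  do.call(prep_protocol, cfg$prep)
  do.call(response_model, cfg$model)
  do.call(study_design, c(cfg$design, list(seed = cfg$seed)))
  do.call(intake_scenario, cfg$intake)
  if (length(unique(cfg$calibration_levels)) < 5) {
    abort("Need at least 5 distinct calibration levels.",
          class = "caffval_degenerate_design")
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The JSON round trip is the identity on the configuration.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[setdiff(names(raw), character())])
}

cal_response <- function(levels, model, noise_sd, seed, simulate_traces) {
  if (!simulate_traces) {
    return(generate_calibration_set(levels, model, seed = seed))
  }
  areas <- purrr::map_dbl(seq_along(levels), function(i) {
    chrom <- generate_chromatogram(levels[i], model, noise_sd = noise_sd,
                                   seed = derive_seed(seed, paste0("trace", i)))
    measure_peak_area(chrom, model$retention_time,
                      min_height = max(5, 20 * noise_sd))$area
  })
  tibble::tibble(conc_mg_L = levels, response = areas)
}

#' Run the full validation study
#'
#' Executes, in order: simulation of the calibration series (external and
#' standard-addition), calibration fitting with the matrix-effect slope
#' t-test and LOD/LOQ, the fortified validation study with per-level
#' precision (HORRAT) and recovery, the internal QC chart, a per-level
#' Eurachem uncertainty budget, and the dietary-intake arithmetic. The
#' overall fit-for-purpose verdict requires all recoveries acceptable, all
#' HORRAT values below 2, and the QC chart in control.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, intermediate tables and the
#'   report (JSON + Markdown) are written there.
#' @return A `validation_report` (list of result tibbles and verdicts).
#' @examples
#' rep <- run_pipeline(run_config(seed = 42))
#' rep$fit_for_purpose
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  prep <- do.call(prep_protocol, config$prep)
  model <- do.call(response_model, config$model)
  design <- do.call(study_design,
                    c(config$design, list(seed = derive_seed(config$seed, "study"))))
  ucfg <- config$uncertainty

  # --- calibration ---------------------------------------------------------
  cal_ext <- cal_response(config$calibration_levels, model, config$noise_sd,
                          derive_seed(config$seed, "cal_ext"),
                          config$simulate_traces)
  sa_model <- response_model(
    slope = model$slope * config$matrix_slope_factor,
    intercept = model$intercept, injection_cv = model$injection_cv,
    retention_time = model$retention_time, peak_sigma = model$peak_sigma)
  cal_sa <- cal_response(config$calibration_levels, sa_model, config$noise_sd,
                         derive_seed(config$seed, "cal_sa"),
                         config$simulate_traces)
  fit_ext <- fit_calibration(cal_ext, mode = "external")
  fit_sa <- fit_calibration(cal_sa, mode = "standard_addition")
  slope_test <- compare_slopes(fit_ext, fit_sa)
  lod_mg_L <- lod(fit_ext)
  loq_mg_L <- loq(fit_ext)
  limits <- dplyr::bind_cols(
    tibble::tibble(quantity = c("LOD", "LOQ")),
    extract_to_sample(c(lod_mg_L, loq_mg_L), prep)
  )

  # --- validation study ----------------------------------------------------
  study <- generate_validation_study(design, prep, model)
  precision <- purrr::map_dfr(design$spike_levels,
                              function(l) precision_summary(study, l))
  recov <- purrr::map_dfr(design$spike_levels, function(l) recovery(study, l))

  # --- QC chart ------------------------------------------------------------
  qc_truth <- design$background_content +
    config$qc$spike_pct *
      design$true_recovery_per_level[match(config$qc$spike_pct,
                                           design$spike_levels)]
  if (is.na(qc_truth)) qc_truth <- design$background_content + config$qc$spike_pct
  qc_all <- generate_qc_series(config$qc$n_baseline + config$qc$n_monitor,
                               qc_truth, config$qc$cv,
                               seed = derive_seed(config$seed, "qc"))
  chart <- if (config$qc$cv > 0) {
    build_control_chart(qc_all[seq_len(config$qc$n_baseline), ])
  } else {
    # deterministic QC series has no empirical spread; chart against a
    # nominal SD so the (constant) points are evaluable
    build_control_chart(center = qc_truth, sd = 0.01 * qc_truth)
  }
  chart <- evaluate_chart(chart, qc_all[-seq_len(config$qc$n_baseline), ])

  # --- uncertainty budgets, one per level ---------------------------------
  budgets <- purrr::map_dfr(seq_along(design$spike_levels), function(i) {
    total_pct <- design$background_content + design$spike_levels[i]
    conc <- sample_to_extract(total_pct * 10000, prep)
    comps <- c(
      mass = u_mass(ucfg$balance_tolerance, prep$sample_mass),
      volume = u_volume(ucfg$glassware_tolerance, prep$back_extraction_volume,
                        ucfg$temp_coefficient, ucfg$temp_range),
      calibration = u_calibration(fit_ext, conc),
      bias = u_bias(recov[i, ], variant = ucfg$u_bias_variant),
      precision = u_precision(precision[i, ])
    )
    if (ucfg$stock_standard > 0) comps["stock_standard"] <- ucfg$stock_standard
    b <- combine_uncertainty(comps, k = ucfg$k)
    tibble::tibble(level = design$spike_levels[i], !!!as.list(comps),
                   combined = b$combined, expanded = b$expanded)
  })

  # --- intake --------------------------------------------------------------
  scenario <- do.call(intake_scenario, config$intake)
  intake <- dplyr::bind_cols(tibble::tibble(daily_mg = daily_intake(scenario)),
                             weekly_intake(scenario))

  verdict <- all(recov$acceptable) && all(precision$acceptable) &&
    isTRUE(chart$in_control)
  report <- structure(
    list(
      calibration = dplyr::bind_rows(
        dplyr::mutate(glance(fit_ext), mode = "external",
                      slope = fit_ext$slope, intercept = fit_ext$intercept),
        dplyr::mutate(glance(fit_sa), mode = "standard_addition",
                      slope = fit_sa$slope, intercept = fit_sa$intercept)
      ),
      slope_comparison = slope_test,
      limits = limits,
      precision = precision,
      recovery = recov,
      budgets = budgets,
      qc_chart = chart,
      intake = intake,
      fit_for_purpose = verdict,
      provenance = list(seed = config$seed, config_hash = rlang::hash(unclass(config)),
                        package_version = as.character(utils::packageVersion("caffval")))
    ),
    class = "validation_report"
  )
  if (!is.null(out_dir)) write_report(report, study, cal_ext, qc_all, out_dir)
  report
}

write_report <- function(report, study, cal_ext, qc_all, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(cal_ext),
                   file.path(out_dir, "calibration.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(study),
                   file.path(out_dir, "validation_study.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(qc_all),
                   file.path(out_dir, "qc_series.csv"), row.names = FALSE)
  json <- list(
    calibration = report$calibration, slope_comparison = report$slope_comparison,
    limits = report$limits, precision = report$precision,
    recovery = report$recovery, budgets = report$budgets,
    qc = list(center = report$qc_chart$center, sd = report$qc_chart$sd,
              in_control = report$qc_chart$in_control,
              trend = report$qc_chart$trend),
    intake = report$intake, fit_for_purpose = report$fit_for_purpose,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- utils::capture.output(print(report))
  writeLines(c("# Validation report", "", "```", md, "```"),
             file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Method validation report ==\n\n-- Calibration --\n")
  print(as.data.frame(x$calibration), row.names = FALSE)
  cat("\n-- Matrix effect (slope t-test) --\n")
  print(as.data.frame(x$slope_comparison), row.names = FALSE)
  cat("\n-- Detection/quantification limits --\n")
  print(as.data.frame(x$limits), row.names = FALSE)
  cat("\n-- Precision (HORRAT) --\n")
  print(as.data.frame(x$precision), row.names = FALSE)
  cat("\n-- Recovery --\n")
  print(as.data.frame(x$recovery), row.names = FALSE)
  cat("\n-- Uncertainty budgets (relative %) --\n")
  print(as.data.frame(x$budgets), row.names = FALSE)
  cat("\n-- Internal QC --\n")
  print(x$qc_chart)
  cat("\n-- Intake --\n")
  print(as.data.frame(x$intake), row.names = FALSE)
  cat(sprintf("\nOverall verdict: %s\n",
              if (x$fit_for_purpose) "fit for purpose" else "NOT fit for purpose"))
  invisible(x)
}
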