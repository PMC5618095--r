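#' Build a Shewhart internal quality-control chart
#'
#' The chart centre and standard deviation are estimated from a baseline QC
#' series (mean and sample SD of at least 8 points) or fixed externally.
#' Warning limits sit at centre +/- 2 SD and action limits at +/- 3 SD.
#'
#' @param baseline_points Data frame with a `measured_pct` column (the
#'   baseline QC series), or `NULL` when `center` and `sd` are given.
#' @param center,sd Optional fixed chart parameters; both must be supplied to
#'   bypass the baseline requirement, and `sd` must be positive.
#' @return A `control_chart` with `center`, `sd`, `warning_limits`,
#'   `action_limits`, an empty `points` tibble and `in_control = NA` until
#'   points are evaluated.
#' @examples
#' qc <- generate_qc_series(12, 2.3, 0.03, seed = 1)
#' build_control_chart(qc)
#' @export
build_control_chart <- function(baseline_points = NULL, center = NULL, sd = NULL) {
  if (is.null(center) != is.null(sd)) {
    abort("Supply both `center` and `sd`, or neither.",
          class = "caffval_invalid_argument")
  }
  if (is.null(center)) {
    if (is.null(baseline_points) || nrow(baseline_points) < 8) {
      abort("Need at least 8 baseline QC points (or a fixed center/sd).",
            class = "caffval_insufficient_baseline")
    }
    x <- baseline_points$measured_pct
    center <- mean(x)
    sd <- stats::sd(x)
    if (sd == 0) {
      abort("Degenerate baseline: zero spread gives no usable control limits.",
            class = "caffval_degenerate_baseline")
    }
  } else {
    assert_scalar_number(sd, "sd", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(center = center, sd = sd,
         warning_limits = c(center - 2 * sd, center + 2 * sd),
         action_limits = c(center - 3 * sd, center + 3 * sd),
         points = tibble::tibble(run_index = integer(), measured_pct = double(),
                                 flag = character()),
         in_control = NA, trend = FALSE),
    class = "control_chart"
  )
}

#' Evaluate QC points against a control chart
#'
#' Each point is flagged `ok`, `warning` (beyond +/- 2 SD) or `action`
#' (beyond +/- 3 SD). The system is in control when at most 5 % of all
#' evaluated points exceed the warning limits and none exceeds the action
#' limits. A run of 7 or more consecutive points on one side of the centre
#' is reported as an advisory trend flag, not part of the verdict.
#'
#' @param chart A `control_chart`.
#' @param new_points Data frame with `measured_pct` (and optionally
#'   `run_index`).
#' @return The chart with `points`, `in_control` and `trend` updated.
#' @examples
#' qc <- generate_qc_series(30, 2.3, 0.03, seed = 1)
#' chart <- build_control_chart(qc[1:10, ])
#' evaluate_chart(chart, qc[11:30, ])
#' @export
evaluate_chart <- function(chart, new_points) {
  stopifnot(inherits(chart, "control_chart"))
  x <- new_points$measured_pct
  ri <- new_points[["run_index"]] %||% seq_along(x)
  dev <- abs(x - chart$center)
  flag <- dplyr::case_when(
    dev > 3 * chart$sd ~ "action",
    dev > 2 * chart$sd ~ "warning",
    TRUE ~ "ok"
  )
  pts <- dplyr::bind_rows(
    chart$points,
    tibble::tibble(run_index = as.integer(ri), measured_pct = x, flag = flag)
  )
  frac_warn <- mean(pts$flag != "ok")
  chart$points <- pts
  chart$in_control <- frac_warn <= 0.05 && !any(pts$flag == "action")
  side <- sign(pts$measured_pct - chart$center)
  runs <- rle(side[side != 0])
  chart$trend <- any(runs$lengths >= 7)
  chart
}

#' @export
print.control_chart <- function(x, ...) {
  cat(sprintf("Shewhart QC chart: center %.4g, sd %.4g\n", x$center, x$sd))
  cat(sprintf("  warning (%.4g, %.4g); action (%.4g, %.4g)\n",
              x$warning_limits[1], x$warning_limits[2],
              x$action_limits[1], x$action_limits[2]))
  if (nrow(x$points)) {
    cat(sprintf("  %d points: %d warning, %d action; in control: %s%s\n",
                nrow(x$points), sum(x$points$flag == "warning"),
                sum(x$points$flag == "action"), x$in_control,
                if (x$trend) " (advisory: trend run >= 7)" else ""))
  }
  invisible(x)
}

#' Plot a control chart
#'
#' @param object A `control_chart` with evaluated points.
#' @param ... Unused.
#' @return A ggplot object with centre, warning and action lines.
#' @export
autoplot.control_chart <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$run_index, y = .data$measured_pct)) +
    ggplot2::geom_hline(yintercept = object$center, colour = "grey30") +
    ggplot2::geom_hline(yintercept = object$warning_limits,
                        linetype = "dashed", colour = "orange") +
    ggplot2::geom_hline(yintercept = object$action_limits,
                        linetype = "dotted", colour = "red") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag)) +
    ggplot2::scale_colour_manual(
      values = c(ok = "black", warning = "orange", action = "red")) +
    ggplot2::labs(x = "Run index", y = "QC result (%w/w)", colour = NULL) +
    ggplot2::theme_minimal()
}
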