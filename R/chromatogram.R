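#' Validate and tag a time/signal table as a chromatogram
#'
#' @param df Data frame with numeric columns `time_min` (strictly increasing)
#'   and `signal`, at least 10 rows.
#' @return The input as a `chromatogram` tibble.
#' @export
as_chromatogram <- function(df) {
  if (!all(c("time_min", "signal") %in% names(df))) {
    abort("A chromatogram needs `time_min` and `signal` columns.",
          class = "caffval_invalid_argument")
  }
  if (nrow(df) < 10) {
    abort("A chromatogram needs at least 10 samples.",
          class = "caffval_invalid_argument")
  }
  if (any(diff(df$time_min) <= 0)) {
    abort("`time_min` must be strictly increasing.",
          class = "caffval_invalid_argument")
  }
  out <- tibble::as_tibble(df)
  if (!inherits(out, "chromatogram")) class(out) <- c("chromatogram", class(out))
  out
}

#' Estimate the chromatographic baseline
#'
#' Morphological opening (rolling minimum followed by rolling maximum over
#' `window` minutes) flattens peaks narrower than the window while tracking
#' slow drift; a final rolling mean smooths the staircase. The result hugs
#' the signal from below up to the smoothing tolerance.
#'
#' @param chrom A chromatogram.
#' @param window Structuring window in minutes; must exceed the sampling
#'   interval and be comfortably wider than the peaks of interest.
#' @return Numeric vector of baseline values, same length as the trace.
#' @export
estimate_baseline <- function(chrom, window = 0.5) {
  chrom <- as_chromatogram(chrom)
  dt <- median(diff(chrom$time_min))
  span <- diff(range(chrom$time_min))
  if (window <= dt) {
    abort("`window` must exceed the sampling interval.",
          class = "caffval_invalid_argument")
  }
  if (window > span) {
    abort("`window` is larger than the trace span.",
          class = "caffval_invalid_argument")
  }
  k <- max(3L, as.integer(round(window / dt)))
  if (k %% 2 == 0) k <- k + 1L
  x <- chrom$signal
  op <- roll_extremum(roll_extremum(x, k, min), k, max)
  roll_mean_centered(op, k)
}

# Centered rolling min/max in O(n) (van Herk-Gil-Werman): block-wise prefix
# and suffix running extrema combined across the window. Edges use
# replication padding.
roll_extremum <- function(x, k, fun = min) {
  n <- length(x)
  k2 <- k %/% 2
  xp <- c(rep(x[1], k2), x, rep(x[n], k2))
  len <- length(xp)
  pad_val <- if (identical(fun, min)) Inf else -Inf
  nb <- ceiling(len / k)
  xpp <- c(xp, rep(pad_val, nb * k - len))
  m <- matrix(xpp, nrow = k)
  runner <- if (identical(fun, min)) cummin else cummax
  L <- as.vector(apply(m, 2, runner))
  R <- as.vector(apply(m[k:1, , drop = FALSE], 2, runner)[k:1, , drop = FALSE])
  comb <- if (identical(fun, min)) pmin else pmax
  comb(R[seq_len(len - k + 1)], L[k:len])
}

roll_mean_centered <- function(x, k) {
  n <- length(x)
  k2 <- k %/% 2
  xp <- c(rep(x[1], k2), x, rep(x[n], k2))
  out <- stats::filter(xp, rep(1 / k, k), sides = 2)
  as.numeric(out[(k2 + 1):(k2 + n)])
}

#' Subtract the estimated baseline from a chromatogram
#'
#' @inheritParams estimate_baseline
#' @return The chromatogram with `signal` replaced by the baseline-subtracted
#'   trace and the baseline stored in column `baseline`.
#' @export
subtract_baseline <- function(chrom, window = 0.5) {
  chrom <- as_chromatogram(chrom)
  b <- estimate_baseline(chrom, window)
  chrom$baseline <- b
  chrom$signal <- chrom$signal - b
  chrom
}

#' Detect peaks in a baseline-subtracted chromatogram
#'
#' Local maxima above `min_height` become peak apexes; each peak's bounds
#' extend outward to the nearest baseline return (signal falling below
#' `boundary_frac` of the apex height, or a local minimum).
#'
#' @param chrom A baseline-subtracted chromatogram.
#' @param min_height Minimum apex height, signal units.
#' @param boundary_frac Fraction of apex height treated as baseline return
#'   (default 0.005).
#' @return A tibble of peaks (`apex_time`, `start_time`, `end_time`, `height`,
#'   `area`), sorted by apex time; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(chrom, min_height, boundary_frac = 0.005) {
  chrom <- as_chromatogram(chrom)
  x <- chrom$signal
  tt <- chrom$time_min
  n <- length(x)
  empty <- tibble::tibble(apex_time = double(), start_time = double(),
                          end_time = double(), height = double(),
                          area = double())
  # strict local maxima (plateaus take their first index)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  idx <- which(is_max & x > min_height)
  if (!length(idx)) return(empty)
  peaks <- purrr::map_dfr(idx, function(i) {
    thresh <- boundary_frac * x[i]
    slack <- 0.02 * x[i] # tolerate noise micro-upticks on the flanks
    lo <- i
    while (lo > 1 && x[lo - 1] > thresh && x[lo - 1] <= x[lo] + slack) lo <- lo - 1
    hi <- i
    while (hi < n && x[hi + 1] > thresh && x[hi + 1] <= x[hi] + slack) hi <- hi + 1
    tibble::tibble(apex_time = tt[i], start_time = tt[lo], end_time = tt[hi],
                   height = x[i],
                   area = pracma::trapz(tt[lo:hi], pmax(x[lo:hi], 0)))
  })
  # merge apexes that resolved to the same bounds (noise-split maxima)
  peaks <- peaks |>
    dplyr::group_by(.data$start_time, .data$end_time) |>
    dplyr::slice_max(.data$height, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$apex_time)
  peaks
}

#' Integrate a peak by the trapezoid rule above the local baseline
#'
#' Negative baseline-subtracted samples are clipped to zero so the area is
#' always non-negative.
#'
#' @param chrom A baseline-subtracted chromatogram.
#' @param peak One-row data frame (or list) with `start_time` and `end_time`
#'   inside the trace.
#' @return Peak area in signal·min.
#' @export
integrate_peak <- function(chrom, peak) {
  chrom <- as_chromatogram(chrom)
  st <- peak$start_time[1]
  en <- peak$end_time[1]
  rng <- range(chrom$time_min)
  if (st < rng[1] || en > rng[2] || st >= en) {
    abort("Peak bounds fall outside the trace.",
          class = "caffval_invalid_argument")
  }
  sel <- chrom$time_min >= st & chrom$time_min <= en
  pracma::trapz(chrom$time_min[sel], pmax(chrom$signal[sel], 0))
}

#' Match the analyte peak by retention time
#'
#' Returns the peak whose apex lies nearest `expected_rt` within
#' `tolerance`; ties within the tolerance are broken toward the larger area.
#'
#' @param peaks Peak tibble from [detect_peaks()].
#' @param expected_rt Expected retention time, minutes.
#' @param tolerance Matching half-window in minutes (> 0, default 0.1).
#' @return A one-row peak tibble, or `NULL` when no peak qualifies.
#' @export
match_analyte <- function(peaks, expected_rt, tolerance = 0.1) {
  assert_scalar_number(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  if (is.null(peaks) || nrow(peaks) == 0) return(NULL)
  cand <- dplyr::filter(peaks, abs(.data$apex_time - expected_rt) <= tolerance)
  if (nrow(cand) == 0) return(NULL)
  d <- abs(cand$apex_time - expected_rt)
  best <- which(d <= min(d) + 1e-12)
  if (length(best) > 1) best <- best[which.max(cand$area[best])]
  cand[best, ]
}

#' Measure the analyte peak area of a raw chromatogram
#'
#' Convenience wrapper: baseline subtraction, peak detection, retention-time
#' matching, trapezoidal integration.
#'
#' @param chrom A raw chromatogram.
#' @param expected_rt Expected analyte retention time, minutes.
#' @param min_height Detection threshold, signal units.
#' @param window Baseline window, minutes.
#' @param tolerance Retention-time matching tolerance, minutes.
#' @return One-row tibble with `area`, `apex_time`, `height`; `area = 0` with
#'   `NA` apex when no analyte peak is found.
#' @export
measure_peak_area <- function(chrom, expected_rt, min_height = 5,
                              window = 0.5, tolerance = 0.1) {
  bs <- subtract_baseline(chrom, window)
  pk <- match_analyte(detect_peaks(bs, min_height), expected_rt, tolerance)
  if (is.null(pk)) {
    return(tibble::tibble(area = 0, apex_time = NA_real_, height = NA_real_))
  }
  tibble::tibble(area = integrate_peak(bs, pk),
                 apex_time = pk$apex_time, height = pk$height)
}

#' Plot a chromatogram
#'
#' @param object A `chromatogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (min)", y = "FID signal") +
    ggplot2::theme_minimal()
}
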