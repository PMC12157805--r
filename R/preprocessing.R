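# Outlier filtering and wall-clock minute binning of weight series.

#' Remove outliers beyond k standard deviations
#'
#' Single-pass filter: points whose distance from the period mean exceeds
#' `k` times the sample standard deviation (n-1 denominator) of the period
#' are dropped. The statistics are computed once from the full input; the
#' filter is deliberately not re-iterated on its own output.
#'
#' @param values numeric vector (one filtering period, e.g. one minute of
#'   resultant weights).
#' @param k SD multiple (default 2).
#' @return List with `values` (survivors, order preserved), `keep` (logical
#'   mask over the input) and `n_removed`.
#' @examples
#' remove_outliers(c(rep(0, 9), 50))$n_removed  # 1
#' remove_outliers(c(0, 0, 0, 100))$n_removed   # 0 (bound = 125)
#' @export
remove_outliers <- function(values, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("k must be a positive number", call. = FALSE)
  }
  n <- length(values)
  if (n < 2) {
    return(list(values = values, keep = rep(TRUE, n), n_removed = 0L))
  }
  m <- mean(values)
  s <- stats::sd(values)
  keep <- if (s == 0) rep(TRUE, n) else abs(values - m) <= k * s
  list(values = values[keep], keep = keep, n_removed = sum(!keep))
}

#' Bin a weight series into wall-clock minutes
#'
#' Raw files carry only elapsed microseconds, so an absolute anchor
#' (`start_clock`, when the recording started; 11:00 in the default protocol)
#' converts each sample to a wall-clock minute. Minutes are half-open: a
#' sample exactly on a boundary belongs to the later minute. Minutes with no
#' samples inside the recorded span are preserved with `n_samples = 0`.
#'
#' @param series a `weight_series` from [convert_to_weight()] (or any
#'   data.frame with a `t_us` column and monotone timestamps).
#' @param start_clock recording start time (`"HH:MM"` or minutes since
#'   midnight).
#' @param duration_min optional recorded duration in minutes; defaults to the
#'   span implied by the last timestamp.
#' @return An object of class `minute_groups`: list with `series` (the input
#'   plus `minute_index` and `clock_min` columns) and `minutes` (one row per
#'   minute: `minute_index`, `clock_min`, `n_samples`), plus the anchor as an
#'   attribute.
#' @export
bin_by_minute <- function(series, start_clock = "11:00", duration_min = NULL) {
  stopifnot(is.data.frame(series), "t_us" %in% names(series))
  start <- clock_minute(start_clock)
  n <- nrow(series)
  minute_index <- if (n > 0) as.integer(series$t_us %/% 6e7) else integer(0)
  if (n > 1 && is.unsorted(minute_index)) {
    stop("series timestamps must be monotone", call. = FALSE)
  }
  n_min <- if (!is.null(duration_min)) as.integer(duration_min)
           else if (n == 0) 0L else max(minute_index) + 1L
  series$minute_index <- minute_index
  series$clock_min <- (start + minute_index) %% 1440L
  idx <- seq_len(n_min) - 1L
  counts <- tabulate(minute_index + 1L, nbins = n_min)
  minutes <- data.frame(minute_index = idx,
                        clock_min = (start + idx) %% 1440L,
                        n_samples = counts)
  structure(list(series = series, minutes = minutes),
            start_clock = start, class = "minute_groups")
}

#' @export
print.minute_groups <- function(x, ...) {
  cat("Minute-binned series:", nrow(x$minutes), "minutes,",
      nrow(x$series), "samples; start",
      format_clock(attr(x, "start_clock")), "\n")
  invisible(x)
}

#' Effective per-minute sampling rate
#'
#' The acquisition hardware fluctuates around its nominal rate; the effective
#' rate of a minute is simply its sample count divided by 60 s.
#'
#' @param n_samples sample count(s) per minute, or a `minute_groups` object.
#' @return Rate(s) in Hz.
#' @export
effective_rate <- function(n_samples) {
  if (inherits(n_samples, "minute_groups")) n_samples <- n_samples$minutes$n_samples
  n_samples / 60
}
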