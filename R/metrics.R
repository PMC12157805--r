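# Minute-level SPA statistics: absolute weight changes, their per-minute sum
# (SWC) and mean (MWC), dispersion (SD-WC, CV-WC), per-day baseline-bias
# correction, daily summaries and trapezoidal AUC.

#' Per-step absolute weight changes within one minute
#'
#' The elementary SPA signal: the absolute difference between consecutive
#' weight samples. Two cross-cell combinations are supported. The default,
#' `"per_cell_abs"`, takes the modulus of each cell's change and sums the
#' three — this registers weight redistribution across the plate (ambulation)
#' even when the resultant weight is unchanged. `"resultant_first"` sums the
#' cells first and takes the modulus of the resultant's change, so pure
#' redistribution cancels. Differences are only ever formed between
#' consecutive samples of the same minute.
#'
#' @param weights matrix or data.frame of one minute's per-cell weights
#'   (columns `w1`, `w2`, `w3`, or simply three numeric columns), in grams.
#' @param combine `"per_cell_abs"` (default) or `"resultant_first"`.
#' @return Numeric vector of `nrow(weights) - 1` nonnegative per-step changes
#'   (grams); empty when fewer than 2 samples.
#' @examples
#' w <- cbind(w1 = c(0, 1), w2 = c(1, 0), w3 = c(5, 5))
#' weight_changes(w)                      # 2: both cells moved
#' weight_changes(w, "resultant_first")   # 0: resultant unchanged
#' @export
weight_changes <- function(weights, combine = c("per_cell_abs", "resultant_first")) {
  combine <- match.arg(combine)
  w <- as.matrix(weights)
  if (!is.null(colnames(w)) && all(c("w1", "w2", "w3") %in% colnames(w))) {
    w <- w[, c("w1", "w2", "w3"), drop = FALSE]
  }
  stopifnot(ncol(w) == 3)
  if (nrow(w) < 2) return(numeric(0))
  if (combine == "per_cell_abs") {
    abs(diff(w[, 1])) + abs(diff(w[, 2])) + abs(diff(w[, 3]))
  } else {
    abs(diff(w[, 1] + w[, 2] + w[, 3]))
  }
}

#' Sum of weight changes (SWC)
#'
#' The summation strategy: one minute's SPA is the sum of its absolute
#' per-step weight changes. Sensitive to the number of samples collected in
#' the minute, hence to sampling-rate fluctuation.
#'
#' @param changes nonnegative per-step changes (grams) from [weight_changes()].
#' @return SWC in grams; 0 for an empty minute.
#' @export
swc <- function(changes) {
  if (length(changes) == 0) return(0)
  sum(changes)
}

#' Mean of weight changes (MWC)
#'
#' SWC divided by the number of per-step differences, making the statistic
#' robust to fluctuations in samples-per-minute: duplicating every change
#' (as a doubled sampling rate would) doubles SWC but leaves MWC unchanged.
#' A minute of N samples has N - 1 differences; the divisor is that count,
#' preserving the exact identity `swc = mwc * n_diffs`.
#'
#' @inheritParams swc
#' @return MWC in grams per sample-step; 0 for an empty minute.
#' @export
mwc <- function(changes) {
  if (length(changes) == 0) return(0)
  mean(changes)
}

#' Dispersion of within-minute weight changes
#'
#' Standard deviation (sample, n-1) and coefficient of variation
#' (`100 * sd / mean`, percent) of the nonnegative change sequence. Minutes
#' with identical MWC can differ markedly in CV, revealing signal structure
#' the mean alone hides. CV is undefined (returned `NA`) when the mean is 0.
#'
#' @inheritParams swc
#' @return List with `sd_wc` (grams; `NA` with fewer than 2 changes) and
#'   `cv_wc` (percent; `NA` when undefined).
#' @export
dispersion <- function(changes) {
  if (length(changes) < 2) {
    return(list(sd_wc = NA_real_, cv_wc = NA_real_))
  }
  s <- stats::sd(changes)
  m <- mean(changes)
  list(sd_wc = s, cv_wc = if (m == 0) NA_real_ else 100 * s / m)
}

# per-group sample SD from sums/sums of squares (guarding tiny counts and
# negative rounding); used by the vectorised minute aggregation
.group_sd <- function(sum_x, sum_x2, n) {
  v <- (sum_x2 - sum_x^2 / pmax(n, 1)) / (n - 1)
  out <- sqrt(pmax(v, 0))
  out[n < 2] <- NA_real_
  out
}

#' Minute-level SPA records for one recording day
#'
#' The per-day workhorse: filters outliers, forms within-minute weight
#' changes and computes every minute's SWC, MWC, SD-WC and CV-WC plus its
#' phase label. Outlier filtering follows the k-SD rule of
#' [remove_outliers()] applied to the resultant weight, with removal
#' propagated to all three cells; the filtering period is the calendar minute
#' by default (local statistics track the nonstationary signal) or the whole
#' day. Removed points are dropped, not interpolated: changes are formed
#' between surviving neighbours, and never across minute boundaries. Minutes
#' with fewer than two surviving samples get `swc = mwc = 0` (flagged by
#' their `n_diffs = 0`) rather than missing values, since the day-minimum
#' baseline correction presumes a value for every minute.
#'
#' @param groups a `minute_groups` object from [bin_by_minute()].
#' @param schedule a [light_schedule()] for phase labelling.
#' @param combine cross-cell combination, see [weight_changes()].
#' @param outlier_k SD multiple for the outlier filter (default 2);
#'   `NULL` disables filtering.
#' @param outlier_period `"minute"` (default) or `"day"`.
#' @return data.frame of class `minute_records`, one row per minute:
#'   `minute_index`, `clock_min`, `clock` (HH:MM), `phase`, `n_samples_raw`,
#'   `n_removed`, `n_samples`, `n_diffs`, `swc`, `mwc`, `sd_wc`, `cv_wc`.
#'   Attributes carry the day/balance identity and total removed count.
#' @export
minute_records <- function(groups, schedule = light_schedule(),
                           combine = c("per_cell_abs", "resultant_first"),
                           outlier_k = 2,
                           outlier_period = c("minute", "day")) {
  stopifnot(inherits(groups, "minute_groups"))
  combine <- match.arg(combine)
  outlier_period <- match.arg(outlier_period)
  ser <- groups$series
  mins <- groups$minutes
  n_min <- nrow(mins)
  grp <- ser$minute_index + 1L

  keep <- rep(TRUE, nrow(ser))
  if (!is.null(outlier_k) && nrow(ser) > 1) {
    if (outlier_period == "day") {
      keep <- remove_outliers(ser$w_total, outlier_k)$keep
    } else {
      n <- tabulate(grp, nbins = n_min)
      s1 <- rowsum(ser$w_total, grp, reorder = FALSE)
      s2 <- rowsum(ser$w_total^2, grp, reorder = FALSE)
      present <- unique(grp)  # grp is monotone, so already ordered
      mu <- sd_ <- rep(NA_real_, n_min)
      mu[present] <- s1[, 1] / n[present]
      sd_[present] <- .group_sd(s1[, 1], s2[, 1], n[present])
      ok_minute <- n[grp] >= 2 & !is.na(sd_[grp]) & sd_[grp] > 0
      keep <- !ok_minute | abs(ser$w_total - mu[grp]) <= outlier_k * sd_[grp]
    }
  }
  removed_per_min <- tabulate(grp[!keep], nbins = n_min)
  w1 <- ser$w1[keep]; w2 <- ser$w2[keep]; w3 <- ser$w3[keep]
  wt <- ser$w_total[keep]
  grp <- grp[keep]

  # within-minute per-step changes between surviving neighbours, vectorised
  n_kept <- length(grp)
  if (n_kept >= 2) {
    same <- grp[-1] == grp[-n_kept]
    step <- if (combine == "per_cell_abs") {
      abs(diff(w1)) + abs(diff(w2)) + abs(diff(w3))
    } else {
      abs(diff(wt))
    }
    step <- step[same]
    step_grp <- grp[-1][same]
  } else {
    step <- numeric(0)
    step_grp <- integer(0)
  }

  n_diffs <- tabulate(step_grp, nbins = n_min)
  swc_v <- mwc_v <- numeric(n_min)
  sd_v <- cv_v <- rep(NA_real_, n_min)
  if (length(step) > 0) {
    ssum <- rowsum(step, step_grp, reorder = FALSE)
    ssq <- rowsum(step^2, step_grp, reorder = FALSE)
    present <- unique(step_grp)
    swc_v[present] <- ssum[, 1]
    mwc_v[present] <- ssum[, 1] / n_diffs[present]
    sd_v[present] <- .group_sd(ssum[, 1], ssq[, 1], n_diffs[present])
    cv_v <- ifelse(mwc_v > 0 & !is.na(sd_v), 100 * sd_v / mwc_v, NA_real_)
  }

  out <- data.frame(minute_index = mins$minute_index,
                    clock_min = mins$clock_min,
                    clock = format_clock(mins$clock_min),
                    phase = assign_phase(mins$clock_min, schedule),
                    n_samples_raw = mins$n_samples,
                    n_removed = removed_per_min,
                    n_samples = mins$n_samples - removed_per_min,
                    n_diffs = n_diffs,
                    swc = swc_v, mwc = mwc_v, sd_wc = sd_v, cv_wc = cv_v)
  structure(out, class = c("minute_records", "data.frame"),
            combine = combine, outlier_k = outlier_k,
            outlier_period = outlier_period,
            n_removed_total = sum(removed_per_min))
}

#' Per-day baseline-bias correction
#'
#' The quietest minute of a day is taken to reflect minimal animal movement,
#' so its SPA is interpreted as that day's system bias and subtracted from
#' every minute of the same day. The corrected day has minimum exactly 0 and
#' unchanged differences between any two minutes.
#'
#' @param day numeric vector of one day's minute MWC values, or a
#'   `minute_records` data.frame (its `mwc` column is corrected into a new
#'   `mwc_corrected` column).
#' @return Same shape as the input with corrected values; the subtracted
#'   bias is attached as attribute `baseline_bias` (and, for data.frame
#'   input, also returned in the `baseline_bias` column-attribute form).
#' @examples
#' baseline_correct(c(5, 7, 9))  # 0 2 4, bias 5
#' @export
baseline_correct <- function(day) {
  if (is.data.frame(day)) {
    if (nrow(day) == 0) stop("cannot baseline-correct an empty day", call. = FALSE)
    bias <- min(day$mwc)
    day$mwc_corrected <- day$mwc - bias
    attr(day, "baseline_bias") <- bias
    return(day)
  }
  if (length(day) == 0) stop("cannot baseline-correct an empty day", call. = FALSE)
  bias <- min(day)
  structure(day - bias, baseline_bias = bias)
}

#' Single daily SPA value
#'
#' Collapses a day to one scalar: the arithmetic mean of its corrected
#' minute-level MWC values over the recorded minutes.
#'
#' @param day numeric vector of corrected minute MWC values, or a corrected
#'   `minute_records` data.frame (uses `mwc_corrected`).
#' @return Daily SPA in grams (per sample-step).
#' @export
daily_value <- function(day) {
  v <- if (is.data.frame(day)) day$mwc_corrected else day
  if (is.null(v) || length(v) == 0) stop("empty day", call. = FALSE)
  mean(v)
}

#' Nadir and acrophase of a day
#'
#' The clock minutes of the day's minimum and maximum SPA. Ties resolve to
#' the earliest recorded minute. On a baseline-corrected day the nadir value
#' is 0 by construction.
#'
#' @param day a corrected `minute_records` data.frame (uses `mwc_corrected`
#'   and `clock_min`), or a numeric vector (positions reported instead of
#'   clock minutes).
#' @return List with `nadir` and `acrophase`, each `(minute, clock, value)`.
#' @export
extremes <- function(day) {
  if (is.data.frame(day)) {
    if (nrow(day) == 0) stop("empty day", call. = FALSE)
    v <- day$mwc_corrected
    if (is.null(v)) v <- day$mwc
    lo <- which.min(v)
    hi <- which.max(v)
    list(nadir = list(minute = day$clock_min[lo], clock = format_clock(day$clock_min[lo]),
                      value = v[lo]),
         acrophase = list(minute = day$clock_min[hi], clock = format_clock(day$clock_min[hi]),
                          value = v[hi]))
  } else {
    if (length(day) == 0) stop("empty day", call. = FALSE)
    lo <- which.min(day)
    hi <- which.max(day)
    list(nadir = list(minute = lo, clock = NA_character_, value = day[lo]),
         acrophase = list(minute = hi, clock = NA_character_, value = day[hi]))
  }
}

#' Trapezoidal area under the daily SPA curve
#'
#' Cumulative SPA over an experiment, by the trapezoidal rule over the
#' ordered daily values with unit (one-day) spacing by default.
#'
#' @param daily_values ordered numeric vector (one value per day, >= 2).
#' @param spacing distance between consecutive values (days).
#' @return AUC in grams x days.
#' @examples
#' auc_trapezoid(c(1, 3))        # 2
#' auc_trapezoid(rep(5, 23))     # 110 = 22 * 5
#' @export
auc_trapezoid <- function(daily_values, spacing = 1) {
  n <- length(daily_values)
  if (n < 2) stop("AUC needs at least 2 values", call. = FALSE)
  sum((daily_values[-1] + daily_values[-n]) / 2) * spacing
}

#' AUC relative to a reference group
#'
#' @param auc_a AUC of the group of interest.
#' @param auc_b reference AUC (set as 100%).
#' @return Percent of reference: `100 * auc_a / auc_b`.
#' @export
relative_auc <- function(auc_a, auc_b) {
  if (any(auc_b == 0)) stop("reference AUC must be nonzero", call. = FALSE)
  100 * auc_a / auc_b
}
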