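# End-to-end analysis: raw streams -> calibrated weights -> minute records
# -> baseline-corrected SPA -> domains, day summaries and heat map.

#' Analyse a multi-day SPA recording
#'
#' Runs the full pipeline on one or more recording days: calibration to
#' grams, minute binning from the recording anchor, outlier filtering,
#' minute-level SWC/MWC/SD-WC/CV-WC, per-day baseline-bias correction,
#' quartile thresholds over the pooled corrected minutes, four-domain
#' classification, and per-day summaries (daily SPA value, nadir and
#' acrophase).
#'
#' @param streams a [raw_stream()], a list of them (one per day), or an
#'   `spa_simulation` from [simulate_raw()] (its streams and exact inverse
#'   calibration are used automatically).
#' @param calibration a `spa_calibration`; mandatory for raw streams, ignored
#'   for a simulation unless supplied explicitly.
#' @param schedule a [light_schedule()].
#' @param start_clock daily recording start.
#' @param combine cross-cell combination, see [weight_changes()].
#' @param outlier_k SD multiple for outlier filtering (`NULL` disables).
#' @param outlier_period `"minute"` or `"day"`.
#' @param thresholds an `spa_thresholds` to classify against, or `NULL`
#'   (default) to compute pooled quartiles from this dataset.
#' @param percentile_method passed to [compute_thresholds()] when thresholds
#'   are computed.
#' @return Object of class `spa_analysis`: list with `minutes` (day-stacked
#'   minute records incl. `mwc_corrected` and `domain`), `days` (per-day
#'   baseline bias, daily value, nadir/acrophase), `thresholds`, and the
#'   analytic choices in `params`.
#' @examples
#' sim <- simulate_raw(simulation_config(n_days = 2, duration_min = 20,
#'                                       seed = 7))
#' fit <- spa_analyze(sim)
#' fit
#' @export
spa_analyze <- function(streams, calibration = NULL,
                        schedule = light_schedule(), start_clock = "11:00",
                        combine = c("per_cell_abs", "resultant_first"),
                        outlier_k = 2, outlier_period = c("minute", "day"),
                        thresholds = NULL, percentile_method = "linear") {
  combine <- match.arg(combine)
  outlier_period <- match.arg(outlier_period)
  if (inherits(streams, "spa_simulation")) {
    if (is.null(calibration)) calibration <- simulated_calibration(streams$config)
    schedule <- streams$config$schedule
    start_clock <- streams$config$start_clock
    streams <- streams$streams
  }
  if (inherits(streams, c("raw_stream", "weight_series"))) streams <- list(streams)
  stopifnot(length(streams) >= 1)

  day_list <- vector("list", length(streams))
  day_rows <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    st <- streams[[i]]
    if (inherits(st, "raw_stream")) {
      if (is.null(calibration)) stop("raw streams require a calibration", call. = FALSE)
      if (nrow(st) == 0) stop("empty raw stream (day ", i, ")", call. = FALSE)
      st <- convert_to_weight(st, calibration)
    }
    day_id <- attr(st, "day_id")
    if (is.null(day_id)) day_id <- names(streams)[i]
    if (is.null(day_id) || !nzchar(day_id)) day_id <- sprintf("day%02d", i)
    groups <- bin_by_minute(st, start_clock = start_clock)
    recs <- minute_records(groups, schedule = schedule, combine = combine,
                           outlier_k = outlier_k, outlier_period = outlier_period)
    recs <- baseline_correct(recs)
    ext <- extremes(recs)
    day_rows[[i]] <- data.frame(day_id = day_id,
                                n_minutes = nrow(recs),
                                n_outliers_removed = attr(recs, "n_removed_total"),
                                baseline_bias = attr(recs, "baseline_bias"),
                                daily_value = daily_value(recs),
                                nadir_clock = ext$nadir$clock,
                                nadir_value = ext$nadir$value,
                                acrophase_clock = ext$acrophase$clock,
                                acrophase_value = ext$acrophase$value)
    recs$day_id <- day_id
    day_list[[i]] <- recs
  }
  minutes <- do.call(rbind, lapply(day_list, as.data.frame))
  days <- do.call(rbind, day_rows)

  pooled <- minutes$mwc_corrected[minutes$phase != "gap"]
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(pooled, method = percentile_method)
  }
  minutes$domain <- classify_domain(minutes$mwc_corrected, thresholds)
  minutes$domain[minutes$phase == "gap"] <- 0L

  structure(list(minutes = minutes, days = days, thresholds = thresholds,
                 params = list(combine = combine, outlier_k = outlier_k,
                               outlier_period = outlier_period,
                               start_clock = start_clock,
                               percentile_method = attr(thresholds, "method"),
                               schedule = schedule)),
            class = "spa_analysis")
}

#' @export
print.spa_analysis <- function(x, ...) {
  cat("SPA analysis:", nrow(x$days), "day(s),", nrow(x$minutes), "minutes",
      sprintf("(combine = %s, outlier k = %s/%s)\n", x$params$combine,
              format(x$params$outlier_k), x$params$outlier_period))
  print(x$thresholds)
  cat("Daily SPA (corrected MWC, g/step):\n")
  print(format(x$days[, c("day_id", "baseline_bias", "daily_value",
                          "nadir_clock", "acrophase_clock")], digits = 4),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.spa_analysis <- function(object, ...) {
  m <- object$minutes[object$minutes$phase != "gap", ]
  phase_tab <- do.call(rbind, lapply(split(m, m$phase), function(d) {
    data.frame(phase = d$phase[1], n_minutes = nrow(d),
               mwc = mean(d$mwc_corrected),
               sd_wc = mean(d$sd_wc, na.rm = TRUE),
               cv_wc = mean(d$cv_wc, na.rm = TRUE))
  }))
  rownames(phase_tab) <- NULL
  out <- list(phases = phase_tab,
              domains = tally_domains(m, "experiment_phase"),
              thresholds = object$thresholds,
              days = object$days)
  class(out) <- "summary.spa_analysis"
  out
}

#' @export
print.summary.spa_analysis <- function(x, ...) {
  cat("Phase summary (mean of per-minute values):\n")
  print(format(x$phases, digits = 4), row.names = FALSE)
  print(x$thresholds)
  cat("Time in domain (whole experiment, per phase):\n")
  print(format(x$domains, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.spa_analysis <- function(x, ...) {
  plot(heatmap_matrix(x$minutes), ...)
}

#' Recording-design arithmetic
#'
#' Phase-minute and data-volume accounting for a recording design: minutes
#' per phase per day under the schedule, totals over the experiment, and the
#' implied sample counts at the nominal rate.
#'
#' @param schedule a [light_schedule()].
#' @param n_days experimental days.
#' @param rate_hz nominal sampling rate.
#' @param n_balances number of balances recording in parallel.
#' @param n_cells_per_balance load cells per balance.
#' @return List: per-day and total dark/light/gap/recorded minutes, recorded
#'   hours, and `samples_per_cell` / `samples_total` at the nominal rate.
#' @examples
#' recording_summary()  # 13800 dark, 16560 light, 30360 min = 506 h
#' @export
recording_summary <- function(schedule = light_schedule(), n_days = 23,
                              rate_hz = 40, n_balances = 2,
                              n_cells_per_balance = 3) {
  n_days <- as.integer(n_days)
  per_day <- table(schedule$phase_by_minute)
  dark <- as.integer(per_day[["dark"]])
  light <- as.integer(per_day[["light"]])
  gap <- as.integer(per_day[["gap"]])
  rec_total <- (dark + light) * n_days
  list(dark_min_per_day = dark, light_min_per_day = light,
       gap_min_per_day = gap,
       dark_min_total = dark * n_days, light_min_total = light * n_days,
       recorded_min_total = rec_total, recorded_hours = rec_total / 60,
       samples_per_cell = rate_hz * 60 * rec_total,
       samples_total = rate_hz * 60 * rec_total * n_balances * n_cells_per_balance)
}

#' Write the analysis tables to CSV
#'
#' Emits the machine-readable outputs: the minute-level table, the day-level
#' table, the three time-in-domain tallies and the heat-map matrix, at full
#' precision.
#'
#' @param analysis an `spa_analysis`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_spa_outputs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "spa_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(minutes = file.path(dir, "minutes.csv"),
             days = file.path(dir, "days.csv"),
             tally_hour = file.path(dir, "tally_hour.csv"),
             tally_day_phase = file.path(dir, "tally_day_phase.csv"),
             tally_phase = file.path(dir, "tally_experiment_phase.csv"),
             heatmap = file.path(dir, "heatmap_matrix.csv"))
  utils::write.csv(analysis$minutes, paths["minutes"], row.names = FALSE)
  utils::write.csv(analysis$days, paths["days"], row.names = FALSE)
  utils::write.csv(tally_domains(analysis$minutes, "hour"), paths["tally_hour"], row.names = FALSE)
  utils::write.csv(tally_domains(analysis$minutes, "day_phase"), paths["tally_day_phase"], row.names = FALSE)
  utils::write.csv(tally_domains(analysis$minutes, "experiment_phase"), paths["tally_phase"], row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(heatmap_matrix(analysis$minutes))),
                   paths["heatmap"], row.names = FALSE)
  invisible(paths)
}
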