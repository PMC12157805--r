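# Quartile thresholds, four-domain SPA classification, time-in-domain
# tallies and actogram-style heat-map matrices.

DOMAIN_LABELS <- c("VL_SPA_D", "L_SPA_D", "M_SPA_D", "H_SPA_D")
DOMAIN_COLORS <- c(missing = "grey85", VL_SPA_D = "#2c7bb6", L_SPA_D = "#abd9e9",
                   M_SPA_D = "#fdae61", H_SPA_D = "#d7191c")

#' Domain thresholds from pooled SPA values
#'
#' Computes the 25th, 50th and 75th percentiles of the pooled corrected
#' minute-level MWC values (across all days and groups) that delimit the four
#' activity domains. Linear interpolation between closest ranks is the
#' default; a nearest-rank alternative is available. The interpolation method
#' is recorded on the result.
#'
#' @param values pooled corrected minute MWC values (>= 4, `NA` dropped).
#' @param method `"linear"` (default) or `"nearest"` rank.
#' @return Object of class `spa_thresholds`: named numeric `(p25, p50, p75)`.
#' @seealso [reference_thresholds()] for the published reference cut points.
#' @export
compute_thresholds <- function(values, method = c("linear", "nearest")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("thresholds need at least 4 values", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.50, 0.75),
                       type = if (method == "linear") 7 else 1, names = FALSE)
  spa_thresholds(q[1], q[2], q[3], method = method)
}

#' Construct domain thresholds directly
#'
#' @param p25,p50,p75 cut points on the corrected MWC scale (grams), ordered.
#' @param method provenance label stored with the thresholds.
#' @return Object of class `spa_thresholds`.
#' @export
spa_thresholds <- function(p25, p50, p75, method = "fixed") {
  if (!(p25 <= p50 && p50 <= p75)) stop("thresholds must be ordered p25 <= p50 <= p75", call. = FALSE)
  structure(c(p25 = p25, p50 = p50, p75 = p75),
            method = method, class = "spa_thresholds")
}

#' Published reference thresholds
#'
#' The cut points 11.0, 16.8 and 22.4 g reported for a pooled 23-day,
#' two-cage mouse dataset; usable for classification without recomputing
#' quartiles.
#'
#' @return Object of class `spa_thresholds`.
#' @export
reference_thresholds <- function() {
  spa_thresholds(11.0, 16.8, 22.4, method = "reference")
}

#' @export
print.spa_thresholds <- function(x, ...) {
  cat(sprintf("SPA domain thresholds (%s): P25 = %g, P50 = %g, P75 = %g\n",
              attr(x, "method"), x[["p25"]], x[["p50"]], x[["p75"]]))
  invisible(x)
}

#' Classify minute SPA into the four activity domains
#'
#' Nested-cut classification of a minute's (corrected) MWC value:
#' below P25 is Very Low (1), at/above P25 and below P50 is Low (2), at/above
#' P50 up to and including P75 is Moderate (3), above P75 is High (4). The
#' inclusive upper bound of the Moderate domain is deliberate and preserved
#' (the other bounds are strict). `NA` inputs (e.g. gap minutes) code to 0.
#'
#' @param spa corrected minute MWC values (grams, nonnegative).
#' @param thresholds an `spa_thresholds` object (default the published
#'   reference cut points).
#' @return Integer domain codes in `{0, 1, 2, 3, 4}` (0 = missing), with the
#'   labels VL/L/M/H_SPA_D retrievable via [domain_labels()].
#' @examples
#' classify_domain(c(10.9, 11.0, 16.8, 22.4, 22.5))  # 1 2 3 3 4
#' @export
classify_domain <- function(spa, thresholds = reference_thresholds()) {
  stopifnot(inherits(thresholds, "spa_thresholds"))
  p25 <- thresholds[["p25"]]; p50 <- thresholds[["p50"]]; p75 <- thresholds[["p75"]]
  out <- ifelse(spa < p25, 1L, ifelse(spa < p50, 2L, ifelse(spa <= p75, 3L, 4L)))
  out[is.na(spa)] <- 0L
  as.integer(out)
}

#' Domain code labels
#'
#' @param codes integer codes in 0..4.
#' @return Factor with levels VL_SPA_D, L_SPA_D, M_SPA_D, H_SPA_D
#'   (`NA` for code 0).
#' @export
domain_labels <- function(codes) {
  factor(DOMAIN_LABELS[ifelse(codes %in% 1:4, codes, NA_integer_)],
         levels = DOMAIN_LABELS)
}

#' Time-in-domain tallies
#'
#' Counts the minutes spent in each of the four domains within non-overlapping
#' windows, in the three reporting shapes used for SPA: per clock hour, per
#' day and phase, or whole-experiment per phase. Gap/missing minutes (code 0)
#' are excluded, so per-window counts sum to the window's recorded minutes
#' (60 for a fully recorded hour).
#'
#' @param minutes data.frame with columns `domain` (codes 0..4), `clock_min`,
#'   `phase` and (for day-resolved windows) `day_id` — e.g. the minute table
#'   of [spa_analyze()].
#' @param window `"hour"`, `"day_phase"` or `"experiment_phase"`.
#' @return data.frame with one row per window: window labels, `n_minutes`,
#'   four domain-count columns and four percent columns (percent of the
#'   window's recorded minutes).
#' @export
tally_domains <- function(minutes, window = c("hour", "day_phase", "experiment_phase")) {
  window <- match.arg(window)
  stopifnot(all(c("domain", "clock_min", "phase") %in% names(minutes)))
  rec <- minutes[minutes$domain %in% 1:4, , drop = FALSE]
  day <- if ("day_id" %in% names(rec)) as.character(rec$day_id) else "all"
  key <- switch(window,
    hour = paste(day, sprintf("%02d:00-%02d:59", rec$clock_min %/% 60,
                              rec$clock_min %/% 60), sep = "|"),
    day_phase = paste(day, rec$phase, sep = "|"),
    experiment_phase = as.character(rec$phase))
  tab <- table(key, factor(rec$domain, levels = 1:4))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), DOMAIN_LABELS))
  n_minutes <- rowSums(counts)
  pct <- 100 * counts / n_minutes
  colnames(pct) <- paste0("pct_", DOMAIN_LABELS)
  out <- data.frame(window = rownames(counts), n_minutes = n_minutes,
                    counts, pct, check.names = FALSE, row.names = NULL)
  if (window != "experiment_phase") {
    parts <- strsplit(out$window, "|", fixed = TRUE)
    out <- cbind(day_id = vapply(parts, `[`, "", 1),
                 stats::setNames(data.frame(vapply(parts, `[`, "", 2)),
                                 if (window == "hour") "hour" else "phase"),
                 out[, -1, drop = FALSE])
  }
  attr(out, "window") <- window
  out
}

#' Minute-by-day heat-map matrix of domain codes
#'
#' Arranges the classified minutes as a matrix with one row per recorded
#' minute of the day (in recording order, starting at the recording anchor)
#' and one column per experimental day — the actogram-style layout in which
#' circadian structure reads as horizontal banding. Gap or missing minutes
#' are coded 0.
#'
#' @param minutes data.frame with `domain`, `minute_index` and `day_id`
#'   columns (e.g. the minute table of [spa_analyze()]).
#' @return Object of class `spa_heatmap`: integer matrix
#'   (recorded-minute-of-day x day) with `clock` row labels and day column
#'   labels.
#' @export
heatmap_matrix <- function(minutes) {
  stopifnot(all(c("domain", "minute_index", "day_id") %in% names(minutes)))
  days <- unique(minutes$day_id)
  n_row <- max(minutes$minute_index) + 1L
  m <- matrix(0L, nrow = n_row, ncol = length(days),
              dimnames = list(NULL, as.character(days)))
  for (j in seq_along(days)) {
    d <- minutes[minutes$day_id == days[j], ]
    m[d$minute_index + 1L, j] <- d$domain
  }
  first_day <- minutes[minutes$day_id == days[1], ]
  clock <- rep(NA_character_, n_row)
  clock[first_day$minute_index + 1L] <- format_clock(first_day$clock_min)
  rownames(m) <- clock
  structure(m, class = c("spa_heatmap", "matrix"))
}

#' Plot a domain heat map
#'
#' Renders the minute-by-day domain matrix with one fixed colour per domain
#' (legend ordered Very Low to High) plus a neutral colour for gap/missing
#' minutes.
#'
#' @param x an `spa_heatmap` matrix.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.spa_heatmap <- function(x, main = "SPA domains (minute x day)", ...) {
  m <- unclass(x)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(0, 4), col = unname(DOMAIN_COLORS),
                  xlab = "day", ylab = "recorded minute of day",
                  main = main, useRaster = TRUE, ...)
  graphics::legend("topright", legend = c("gap/missing", DOMAIN_LABELS),
                   fill = unname(DOMAIN_COLORS), cex = 0.7, bg = "white")
  invisible(x)
}
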