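# Raw balance streams: four numeric columns per line, three load-cell signals
# followed by elapsed time in microseconds (time-last canonical order).

#' Parse a clock time to minutes since midnight
#'
#' Accepts `"HH:MM"` strings, or integers already on the minutes-since-midnight
#' scale (0--1439). Used throughout for light schedules and recording anchors.
#'
#' @param x character vector of `"HH:MM"` times, or integer minutes.
#' @return Integer vector of minutes since midnight.
#' @examples
#' clock_minute("11:00")  # 660
#' clock_minute(c("00:00", "23:59"))
#' @export
clock_minute <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(x)
  } else {
    parts <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
    bad <- vapply(parts, length, 1L) != 3L
    if (any(bad)) {
      stop("invalid clock time(s): ", paste(x[bad], collapse = ", "), call. = FALSE)
    }
    m <- vapply(parts, function(p) as.integer(p[2]) * 60L + as.integer(p[3]), 1L)
  }
  if (any(m < 0L | m > 1439L)) stop("clock minutes must lie in 0..1439", call. = FALSE)
  m
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param m integer vector of minutes since midnight (0--1439).
#' @return Character vector of `"HH:MM"` labels.
#' @export
format_clock <- function(m) {
  m <- as.integer(m) %% 1440L
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

# expand "HH:MM-HH:MM" interval strings (inclusive of both endpoint minutes)
# into the set of minutes-of-day they cover; intervals may wrap midnight
expand_windows <- function(windows) {
  if (length(windows) == 0) return(integer(0))
  out <- lapply(windows, function(w) {
    ends <- strsplit(w, "-", fixed = TRUE)[[1]]
    if (length(ends) != 2) stop("window must be 'HH:MM-HH:MM': ", w, call. = FALSE)
    a <- clock_minute(ends[1])
    b <- clock_minute(ends[2])
    if (a <= b) a:b else c(a:1439L, 0L:b)
  })
  unlist(out)
}

#' Light/dark schedule of the recording day
#'
#' Defines which minutes of the 24 h clock belong to the dark (lamps-off,
#' active) phase, the light (lamps-on, rest) phase, and the daily gap during
#' which recording is paused for husbandry. The default profile is an inverted
#' 12:12 cycle recorded for 22 h/day: dark 11:00--18:59 and 07:00--08:59,
#' light 19:00--06:59, gap 09:00--10:59, i.e. 600 dark, 720 light and 120 gap
#' minutes per day.
#'
#' @param dark,light,gap character vectors of `"HH:MM-HH:MM"` windows
#'   (inclusive at both endpoints; may wrap midnight).
#' @return An object of class `light_schedule`: a list with the window
#'   specifications and a precomputed length-1440 phase lookup
#'   (`phase_by_minute`, factor with levels dark/light/gap).
#' @examples
#' sched <- light_schedule()
#' table(sched$phase_by_minute)
#' @export
light_schedule <- function(dark = c("11:00-18:59", "07:00-08:59"),
                           light = c("19:00-06:59"),
                           gap = c("09:00-10:59")) {
  sets <- list(dark = expand_windows(dark), light = expand_windows(light),
               gap = expand_windows(gap))
  all_min <- unlist(sets)
  if (anyDuplicated(all_min)) {
    stop("schedule windows overlap (minute ",
         format_clock(all_min[duplicated(all_min)][1]), ")", call. = FALSE)
  }
  if (length(all_min) != 1440L) {
    missing <- setdiff(0:1439, all_min)
    stop("schedule does not cover the full day (first uncovered minute ",
         format_clock(missing[1]), ")", call. = FALSE)
  }
  phase <- factor(rep(NA_character_, 1440L), levels = c("dark", "light", "gap"))
  phase[sets$dark + 1L] <- "dark"
  phase[sets$light + 1L] <- "light"
  phase[sets$gap + 1L] <- "gap"
  structure(list(dark = dark, light = light, gap = gap,
                 phase_by_minute = phase),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  n <- table(x$phase_by_minute)
  cat("Light schedule (minutes/day): dark", n[["dark"]],
      "| light", n[["light"]], "| gap", n[["gap"]], "\n")
  cat("  dark :", paste(x$dark, collapse = ", "), "\n")
  cat("  light:", paste(x$light, collapse = ", "), "\n")
  cat("  gap  :", paste(x$gap, collapse = ", "), "\n")
  invisible(x)
}

#' Assign a clock minute to its recording phase
#'
#' Total function on the 24 h clock: every minute maps to exactly one of
#' `"dark"`, `"light"` or `"gap"` under the supplied schedule.
#'
#' @param minute minutes since midnight (integer vector) or `"HH:MM"` strings.
#' @param schedule a [light_schedule()].
#' @return Character vector of phase labels.
#' @examples
#' assign_phase("12:00", light_schedule())  # "dark"
#' assign_phase("20:00", light_schedule())  # "light"
#' @export
assign_phase <- function(minute, schedule = light_schedule()) {
  stopifnot(inherits(schedule, "light_schedule"))
  m <- clock_minute(minute)
  as.character(schedule$phase_by_minute[m %% 1440L + 1L])
}

#' Construct a raw balance stream
#'
#' A raw stream is the unconverted output of one balance for one recording
#' day: per-sample elapsed time in microseconds plus the three load-cell
#' signals on the ADC scale.
#'
#' @param t_us elapsed time in microseconds from stream start (nonnegative,
#'   strictly increasing; stored as numeric since 22 h exceeds the 32-bit
#'   integer range).
#' @param s1,s2,s3 raw load-cell signals (dimensionless, finite).
#' @param balance_id,day_id identifying labels carried through the pipeline.
#' @param nominal_rate_hz expected sampling rate (the acquisition hardware
#'   targets about 40 Hz but fluctuates).
#' @return An object of class `raw_stream`: a data.frame with columns
#'   `t_us`, `s1`, `s2`, `s3` and attributes `balance_id`, `day_id`,
#'   `nominal_rate_hz`.
#' @export
raw_stream <- function(t_us = numeric(0), s1 = numeric(0), s2 = numeric(0),
                       s3 = numeric(0), balance_id = "balance1",
                       day_id = "day1", nominal_rate_hz = 40) {
  if (nominal_rate_hz <= 0) stop("nominal_rate_hz must be > 0", call. = FALSE)
  n <- length(t_us)
  if (length(s1) != n || length(s2) != n || length(s3) != n) {
    stop("t_us, s1, s2, s3 must have equal length", call. = FALSE)
  }
  if (n > 0) {
    if (any(!is.finite(t_us)) || any(t_us < 0)) {
      stop("timestamps must be finite and nonnegative", call. = FALSE)
    }
    if (any(!is.finite(s1)) || any(!is.finite(s2)) || any(!is.finite(s3))) {
      stop("signals must be finite", call. = FALSE)
    }
    dt <- diff(t_us)
    if (n > 1 && any(dt <= 0)) {
      i <- which(dt <= 0)[1] + 1L
      stop("timestamps not strictly increasing at sample ", i, call. = FALSE)
    }
  }
  structure(data.frame(t_us = as.numeric(t_us), s1 = s1, s2 = s2, s3 = s3),
            balance_id = balance_id, day_id = day_id,
            nominal_rate_hz = nominal_rate_hz,
            class = c("raw_stream", "data.frame"))
}

#' @export
print.raw_stream <- function(x, ...) {
  cat("Raw balance stream:", attr(x, "balance_id"), "/", attr(x, "day_id"),
      "-", nrow(x), "samples @ nominal", attr(x, "nominal_rate_hz"), "Hz\n")
  if (nrow(x) > 0) {
    cat("  span:", round((x$t_us[nrow(x)] - x$t_us[1]) / 6e7, 2), "min\n")
    print(utils::head(as.data.frame(x), 3))
  }
  invisible(x)
}

#' Read a raw four-column balance stream
#'
#' Parses the plain-text logger format: one sample per line, four numeric
#' fields separated by whitespace and/or commas. The canonical column order is
#' signals first, time (microseconds) last; loggers that write time in a
#' different column are handled via `time_col`. Strictly increasing timestamps
#' are enforced (a non-monotonic clock indicates an acquisition fault and is
#' an error, never silently reordered). An empty file yields an empty stream.
#'
#' @param source path to the text file (or a connection readable by
#'   [readLines()]).
#' @param nominal_rate_hz expected sampling rate, stored on the stream.
#' @param time_col which of the four columns holds the timestamp (default 4,
#'   the canonical time-last dialect).
#' @param balance_id,day_id labels attached to the stream.
#' @return A [raw_stream()].
#' @export
read_raw_stream <- function(source, nominal_rate_hz = 40, time_col = 4,
                            balance_id = "balance1", day_id = "day1") {
  time_col <- as.integer(time_col)
  if (!time_col %in% 1:4) stop("time_col must be in 1..4", call. = FALSE)
  lines <- readLines(source)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(raw_stream(balance_id = balance_id, day_id = day_id,
                      nominal_rate_hz = nominal_rate_hz))
  }
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1]
    stop("parse error at line ", line_no[i], ": expected 4 fields, found ",
         nf[i], call. = FALSE)
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE))
  if (anyNA(vals)) {
    i <- which(rowSums(is.na(vals)) > 0)[1]
    stop("parse error at line ", line_no[i], ": non-numeric field", call. = FALSE)
  }
  sig <- vals[, setdiff(1:4, time_col), drop = FALSE]
  raw_stream(t_us = vals[, time_col], s1 = sig[, 1], s2 = sig[, 2],
             s3 = sig[, 3], balance_id = balance_id, day_id = day_id,
             nominal_rate_hz = nominal_rate_hz)
}

#' Write a raw stream in the canonical four-column format
#'
#' Emits one sample per line: the three signals (six decimal places) followed
#' by the integer microsecond timestamp, space-separated. Reading a canonical
#' file back and rewriting it reproduces the file byte-identically.
#'
#' @param stream a [raw_stream()].
#' @param sink output file path (or writable connection).
#' @return Invisibly, the number of lines written.
#' @export
write_raw_stream <- function(stream, sink) {
  stopifnot(inherits(stream, "raw_stream"))
  lines <- if (nrow(stream) == 0) character(0) else
    sprintf("%.6f %.6f %.6f %.0f", stream$s1, stream$s2, stream$s3, stream$t_us)
  writeLines(lines, sink)
  invisible(length(lines))
}
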