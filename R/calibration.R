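# Per-load-cell linear calibration: known mass (g) regressed on mean signal,
# y = a*x + b, with R^2 and the standard error of estimate as diagnostics.

#' Fit a single load cell's signal-to-gram calibration line
#'
#' Ordinary least squares of known mass (grams, the response) on the mean
#' recorded signal (ADC scale, the predictor), giving the per-cell conversion
#' `mass = a * signal + b`. The calibration protocol places known masses
#' (typically spanning about 1.8 g to 215 g) at the cell's mounting point and
#' averages the signal over a hold of some seconds; `pairs` holds one row per
#' mass.
#'
#' @param pairs data.frame (or 2-column matrix) with columns `known_mass_g`
#'   and `mean_signal` (in that order if unnamed).
#' @return A list of class `load_cell_fit`: `a` (slope, g per signal unit),
#'   `b` (intercept, g), `r2`, `see_g` (standard error of estimate, g; `NA`
#'   with fewer than 3 points), `n_points`, and the underlying `lm` fit.
#' @seealso [standard_error_of_estimate()], [calibrate_cells()]
#' @export
fit_load_cell <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$known_mass_g)) names(pairs)[1:2] <- c("known_mass_g", "mean_signal")
  y <- pairs$known_mass_g
  x <- pairs$mean_signal
  if (length(x) < 2) stop("calibration needs at least 2 (mass, signal) pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("calibration signals have zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  n <- length(x)
  see <- if (n >= 3) sqrt(ss_res / (n - 2)) else NA_real_
  structure(list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
                 r2 = r2, see_g = see, n_points = n, lm = fit),
            class = "load_cell_fit")
}

#' Standard error of estimate of a calibration fit
#'
#' The root mean squared residual between observed and predicted masses,
#' adjusted for the two degrees of freedom consumed by the line:
#' `sqrt(sum(residual^2) / (n - 2))`, in grams. Requires at least 3
#' calibration points.
#'
#' @param fit a `load_cell_fit` from [fit_load_cell()].
#' @param pairs optional data.frame of `(known_mass_g, mean_signal)` pairs to
#'   evaluate against; defaults to the pairs the fit was made from.
#' @return SEE in grams.
#' @export
standard_error_of_estimate <- function(fit, pairs = NULL) {
  stopifnot(inherits(fit, "load_cell_fit"))
  if (is.null(pairs)) {
    if (fit$n_points < 3) stop("SEE needs at least 3 calibration points", call. = FALSE)
    return(fit$see_g)
  }
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$known_mass_g)) names(pairs)[1:2] <- c("known_mass_g", "mean_signal")
  n <- nrow(pairs)
  if (n < 3) stop("SEE needs at least 3 calibration points", call. = FALSE)
  pred <- fit$a * pairs$mean_signal + fit$b
  sqrt(sum((pairs$known_mass_g - pred)^2) / (n - 2))
}

#' Calibrate the three load cells of one balance
#'
#' Fits one signal-to-gram line per cell and bundles the three fits. R^2 is
#' reported, never enforced; a value below `r2_warn` raises a warning since
#' poor linearity usually indicates an electrical or mechanical defect in the
#' cell or its mounting.
#'
#' @param pairs data.frame with columns `cell_id` (1, 2 or 3), `known_mass_g`
#'   and `mean_signal`; alternatively a list of three per-cell pair tables.
#' @param r2_warn warn when any cell's R^2 falls below this (default 0.999).
#' @return An object of class `spa_calibration`: list of three
#'   `load_cell_fit`s plus a coefficient table.
#' @examples
#' sig <- seq(0, 100000, length.out = 6)
#' pairs <- data.frame(cell_id = rep(1:3, each = 6),
#'                     known_mass_g = rep(sig, 3) * 0.002 + 1,
#'                     mean_signal = rep(sig, 3))
#' cal <- calibrate_cells(pairs)
#' coef(cal)
#' @export
calibrate_cells <- function(pairs, r2_warn = 0.999) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("cell_id", "known_mass_g", "mean_signal") %in% names(pairs)))
    split_pairs <- lapply(1:3, function(i) pairs[pairs$cell_id == i, , drop = FALSE])
  } else {
    stopifnot(is.list(pairs), length(pairs) == 3)
    split_pairs <- pairs
  }
  fits <- lapply(split_pairs, fit_load_cell)
  for (i in 1:3) {
    if (is.finite(fits[[i]]$r2) && fits[[i]]$r2 < r2_warn) {
      warning(sprintf("load cell %d: R^2 = %.5f below %.5f; check for electrical or mechanical defects",
                      i, fits[[i]]$r2, r2_warn), call. = FALSE)
    }
  }
  tab <- data.frame(cell = 1:3,
                    a = vapply(fits, `[[`, 0, "a"),
                    b = vapply(fits, `[[`, 0, "b"),
                    r2 = vapply(fits, `[[`, 0, "r2"),
                    see_g = vapply(fits, `[[`, 0, "see_g"),
                    n_points = vapply(fits, `[[`, 0L, "n_points"))
  structure(list(fits = fits, table = tab), class = "spa_calibration")
}

#' @export
print.spa_calibration <- function(x, digits = 6, ...) {
  cat("Load-cell calibration (mass_g = a * signal + b):\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.spa_calibration <- function(object, ...) {
  m <- as.matrix(object$table[, c("a", "b")])
  rownames(m) <- paste0("cell", 1:3)
  m
}

#' @export
residuals.spa_calibration <- function(object, ...) {
  lapply(object$fits, function(f) stats::residuals(f$lm))
}

#' Predict per-cell weights from raw signals
#'
#' @param object a `spa_calibration`.
#' @param signals matrix or data.frame with three signal columns (cells 1-3).
#' @param ... unused.
#' @return Matrix of per-cell weights in grams.
#' @export
predict.spa_calibration <- function(object, signals, ...) {
  s <- as.matrix(signals)
  stopifnot(ncol(s) == 3)
  w <- vapply(1:3, function(i) object$fits[[i]]$a * s[, i] + object$fits[[i]]$b,
              numeric(nrow(s)))
  if (!is.matrix(w)) w <- matrix(w, ncol = 3)
  colnames(w) <- c("w1", "w2", "w3")
  w
}

#' Convert a raw stream to a weight series
#'
#' Applies each cell's calibration line to its signal column and forms the
#' resultant weight as the sum of the three per-cell weights. Individual cells
#' can legitimately read negative (an off-centre load puts part of the plate
#' under upward tension) while the resultant still equals the applied weight.
#'
#' @param stream a [raw_stream()].
#' @param calibration a `spa_calibration` from [calibrate_cells()].
#' @return An object of class `weight_series`: data.frame with `t_us`, `w1`,
#'   `w2`, `w3`, `w_total` (grams), carrying the stream's identity attributes.
#' @export
convert_to_weight <- function(stream, calibration) {
  stopifnot(inherits(stream, "raw_stream"), inherits(calibration, "spa_calibration"))
  w <- predict(calibration, stream[, c("s1", "s2", "s3")])
  out <- data.frame(t_us = stream$t_us, w1 = w[, 1], w2 = w[, 2], w3 = w[, 3])
  out$w_total <- out$w1 + out$w2 + out$w3
  structure(out, balance_id = attr(stream, "balance_id"),
            day_id = attr(stream, "day_id"),
            nominal_rate_hz = attr(stream, "nominal_rate_hz"),
            class = c("weight_series", "data.frame"))
}

#' Write a calibration model table to CSV
#'
#' @param calibration a `spa_calibration`.
#' @param path output CSV path (columns cell, a, b, r2, see_g, n_points).
#' @return Invisibly, the path.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "spa_calibration"))
  utils::write.csv(calibration$table, path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration model table written by [write_calibration()]
#'
#' @param path CSV path with columns `a` and `b` (one row per cell, in order).
#' @return A `spa_calibration` rebuilt from the stored coefficients (fit
#'   diagnostics preserved if present; the underlying `lm` objects are not).
#' @export
read_calibration <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("a", "b") %in% names(tab)), nrow(tab) == 3)
  if (is.null(tab$cell)) tab$cell <- 1:3
  if (is.null(tab$r2)) tab$r2 <- NA_real_
  if (is.null(tab$see_g)) tab$see_g <- NA_real_
  if (is.null(tab$n_points)) tab$n_points <- NA_integer_
  fits <- lapply(1:3, function(i) {
    structure(list(a = tab$a[i], b = tab$b[i], r2 = tab$r2[i],
                   see_g = tab$see_g[i], n_points = tab$n_points[i], lm = NULL),
              class = "load_cell_fit")
  })
  structure(list(fits = fits,
                 table = tab[, c("cell", "a", "b", "r2", "see_g", "n_points")]),
            class = "spa_calibration")
}
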