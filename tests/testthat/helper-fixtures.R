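# In-code fixtures shared across test files.

# weight series with exact 40 Hz sampling from given per-cell weight matrix
make_weight_series <- function(w, rate_hz = 40, day_id = "day01") {
  w <- as.matrix(w)
  n <- nrow(w)
  structure(data.frame(t_us = round((seq_len(n) - 1) * 1e6 / rate_hz),
                       w1 = w[, 1], w2 = w[, 2], w3 = w[, 3],
                       w_total = rowSums(w)),
            balance_id = "fix", day_id = day_id, nominal_rate_hz = rate_hz,
            class = c("weight_series", "data.frame"))
}

# calibration pairs lying exactly on mass = a*signal + b over the 1.8-215 g
# working range of the rig
exact_line_pairs <- function(a = 2, b = 1, n = 8) {
  signal <- seq((1.8 - b) / a, (215 - b) / a, length.out = n)
  data.frame(known_mass_g = a * signal + b, mean_signal = signal)
}

# identity calibration: weights pass through unchanged (a = 1, b = 0)
identity_calibration <- function() {
  tab <- data.frame(cell = 1:3, a = 1, b = 0, r2 = 1, see_g = 0,
                    n_points = NA_integer_)
  fits <- lapply(1:3, function(i) {
    structure(list(a = 1, b = 0, r2 = 1, see_g = 0, n_points = NA_integer_,
                   lm = NULL), class = "load_cell_fit")
  })
  structure(list(fits = fits, table = tab), class = "spa_calibration")
}

# minute table shaped like spa_analyze()$minutes, for domain/tally tests
make_minutes <- function(domain, clock_min, day_id = "day01",
                         phase = assign_phase(clock_min)) {
  data.frame(day_id = day_id, minute_index = seq_along(domain) - 1L,
             clock_min = clock_min, phase = phase, domain = as.integer(domain))
}

# independent percentile oracle: linear interpolation between closest ranks
oracle_quantile_linear <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# independent static-equilibrium oracle: solve the 3x3 linear system of
# vertical force balance and the two moment equations
oracle_distribute <- function(position, mass_g, geometry) {
  cl <- geometry$cells
  A <- rbind(c(1, 1, 1), cl[, 1], cl[, 2])
  b <- c(mass_g, mass_g * position[1], mass_g * position[2])
  as.numeric(solve(A, b))
}
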