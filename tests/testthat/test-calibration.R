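test_that("exact-line calibration is recovered exactly", {
  fit <- fit_load_cell(exact_line_pairs(a = 2, b = 1))
  expect_equal(fit$a, 2)
  expect_equal(fit$b, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$see_g, 0, tolerance = 1e-10)
})

test_that("least-squares fit matches the hand-computed normal-equations oracle", {
  # pairs (signal, mass) = (0,0),(1,1),(2,1),(3,2)
  # Sxx = 5, Sxy = 3 -> a = 0.6, b = 0.1; residuals (-0.1, 0.3, -0.3, 0.1)
  # SSR = 0.2 -> SEE = sqrt(0.1); Syy = 2 -> r2 = 0.9
  pairs <- data.frame(known_mass_g = c(0, 1, 1, 2), mean_signal = 0:3)
  fit <- fit_load_cell(pairs)
  expect_equal(fit$a, 0.6)
  expect_equal(fit$b, 0.1)
  expect_equal(fit$r2, 0.9)
  expect_equal(fit$see_g, sqrt(0.1))
  expect_equal(standard_error_of_estimate(fit, pairs), sqrt(0.1))
})

test_that("SEE equals the direct residual oracle on noisy data and scales linearly", {
  set.seed(101)
  signal <- seq(900, 107500, length.out = 12)   # spans ~1.8 g to ~215 g at a = 0.002
  resid <- rnorm(12, sd = 0.3)
  resid <- resid - mean(resid) - (signal - mean(signal)) *
    sum((signal - mean(signal)) * resid) / sum((signal - mean(signal))^2)
  # residuals now orthogonal to the line, so OLS recovers (a, b) exactly
  pairs1 <- data.frame(known_mass_g = 0.002 * signal + 0.2 + resid, mean_signal = signal)
  pairs2 <- data.frame(known_mass_g = 0.002 * signal + 0.2 + 2 * resid, mean_signal = signal)
  fit1 <- suppressWarnings(fit_load_cell(pairs1))
  fit2 <- suppressWarnings(fit_load_cell(pairs2))
  oracle_see <- sqrt(sum(resid^2) / (12 - 2))
  expect_equal(fit1$see_g, oracle_see)
  expect_equal(fit2$see_g, 2 * oracle_see)   # doubling every residual doubles SEE
  expect_equal(fit1$a, 0.002)
  expect_lt(fit1$see_g, 0.4)                 # plausibility band of a healthy rig
})

test_that("degenerate calibration input fails loudly", {
  expect_error(fit_load_cell(data.frame(known_mass_g = 1, mean_signal = 1)), "at least 2")
  expect_error(fit_load_cell(data.frame(known_mass_g = 1:3, mean_signal = rep(2, 3))),
               "zero variance")
  fit2 <- fit_load_cell(data.frame(known_mass_g = c(0, 1), mean_signal = c(0, 1)))
  expect_true(is.na(fit2$see_g))
  expect_error(standard_error_of_estimate(fit2), "at least 3")
})

test_that("low linearity triggers the defect warning", {
  pairs <- data.frame(cell_id = rep(1:3, each = 4),
                      known_mass_g = rep(c(0, 1, 1, 2), 3),
                      mean_signal = rep(0:3, 3))
  w <- capture_warnings(calibrate_cells(pairs))
  expect_length(w, 3)               # one defect warning per poorly linear cell
  expect_match(w, "defect", all = TRUE)
  good <- do.call(rbind, lapply(1:3, function(i) cbind(cell_id = i, exact_line_pairs())))
  expect_silent(cal <- calibrate_cells(good))
  expect_equal(unname(coef(cal)[, "a"]), rep(2, 3))
})

test_that("weight conversion applies per-cell lines and sums the resultant", {
  cal <- identity_calibration()
  st <- raw_stream(t_us = c(1, 2), s1 = c(0, -5), s2 = c(0, 20), s3 = c(0, 45))
  w <- convert_to_weight(st, cal)
  expect_equal(w$w_total, c(0, 60))   # one cell negative, sum recovers the load
  expect_equal(w$w_total, w$w1 + w$w2 + w$w3)
})

test_that("simulator inverse-calibration round trip recovers loads to precision", {
  geom <- rig_geometry()
  cfg <- simulation_config(n_days = 1, duration_min = 2, seed = 3)
  pos <- rbind(c(15, 20), c(40, 10), c(55, 44), c(2, 2))
  loads <- distribute_load(pos, 60, geom)
  sig <- sapply(1:3, function(i) (loads[, i] - cfg$calib_b[i]) / cfg$calib_a[i])
  st <- raw_stream(t_us = 1:4, s1 = sig[, 1], s2 = sig[, 2], s3 = sig[, 3])
  w <- convert_to_weight(st, simulated_calibration(cfg))
  expect_equal(as.matrix(w[, c("w1", "w2", "w3")]), loads,
               ignore_attr = TRUE, tolerance = 1e-12)
  # resultant is invariant to where the static load sits on the plate
  expect_equal(w$w_total, rep(60, 4), tolerance = 1e-12)
})

test_that("calibration tables survive a write/read cycle", {
  cal <- calibrate_cells(do.call(rbind, lapply(1:3, function(i)
    cbind(cell_id = i, exact_line_pairs(a = i, b = i / 10)))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(coef(back), coef(cal))
  expect_equal(back$table$see_g, cal$table$see_g, tolerance = 1e-8)
})
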