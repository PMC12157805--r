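sim_small <- simulate_raw(simulation_config(n_days = 2, duration_min = 30,
                                            outlier_rate = 1e-3, seed = 77))

test_that("end-to-end analysis satisfies the conservation invariants", {
  fit <- spa_analyze(sim_small)
  m <- fit$minutes
  expect_equal(nrow(m), 2 * 30)
  # every raw sample is either kept or counted as removed
  for (d in seq_along(sim_small$streams)) {
    day <- m[m$day_id == attr(sim_small$streams[[d]], "day_id"), ]
    expect_equal(sum(day$n_samples) + sum(day$n_removed),
                 nrow(sim_small$streams[[d]]))
    expect_equal(day$n_diffs, pmax(day$n_samples - 1, 0))
  }
  expect_equal(m$swc, m$mwc * m$n_diffs, tolerance = 1e-12)
  # per-day correction: min 0, bias recorded
  for (d in unique(m$day_id)) {
    day <- m[m$day_id == d, ]
    expect_equal(min(day$mwc_corrected), 0)
    expect_equal(day$mwc - day$mwc_corrected,
                 rep(fit$days$baseline_bias[fit$days$day_id == d], nrow(day)))
  }
})

test_that("pooled quartile thresholds put about a quarter of minutes per domain", {
  fit <- spa_analyze(sim_small)
  counts <- table(factor(fit$minutes$domain, levels = 1:4))
  expect_true(all(abs(as.integer(counts) - 15) <= 1))  # 60 minutes, no ties
})

test_that("analysis is deterministic and honours fixed reference thresholds", {
  fit1 <- spa_analyze(sim_small)
  fit2 <- spa_analyze(sim_small)
  expect_identical(fit1$minutes, fit2$minutes)
  fit3 <- spa_analyze(sim_small, thresholds = reference_thresholds())
  expect_equal(as.numeric(fit3$thresholds), c(11.0, 16.8, 22.4))
  expect_equal(fit3$minutes$domain,
               classify_domain(fit3$minutes$mwc_corrected, reference_thresholds()))
})

test_that("analysis objects print, summarise, plot and export", {
  fit <- spa_analyze(sim_small)
  expect_output(print(fit), "SPA analysis: 2 day")
  s <- summary(fit)
  expect_s3_class(s, "summary.spa_analysis")
  expect_output(print(s), "Phase summary")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); expect_no_error(plot(fit)); grDevices::dev.off()

  out <- withr::local_tempdir()
  paths <- write_spa_outputs(fit, out)
  expect_true(all(file.exists(paths)))
  mm <- utils::read.csv(paths[["minutes"]])
  expect_equal(nrow(mm), nrow(fit$minutes))
})

test_that("raw streams and calibration flow through the analysis entry point", {
  cal <- identity_calibration()
  w <- matrix(c(100, 101, 100, 102, 100.5, 101), nrow = 240, ncol = 3)
  ser <- make_weight_series(w, rate_hz = 1 / 1.4)  # 240 samples spanning 6 min
  st <- raw_stream(t_us = ser$t_us, s1 = ser$w1, s2 = ser$w2, s3 = ser$w3)
  fit <- spa_analyze(st, cal, thresholds = reference_thresholds(), outlier_k = NULL)
  expect_equal(nrow(fit$minutes), 6)
  expect_error(spa_analyze(st), "calibration")
  empty <- raw_stream()
  expect_error(spa_analyze(empty, cal), "empty raw stream")
})

test_that("recording-design arithmetic follows the schedule", {
  rs <- recording_summary(n_days = 2)
  expect_equal(rs$recorded_min_total, 2640)
  expect_equal(rs$recorded_hours, 44)
  expect_equal(rs$samples_per_cell, 40 * 60 * 2640)
})

test_that("the command-line wrapper runs simulate and analyze end to end", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  cli <- system.file("cli", "spabalance.R", package = "spabalance")
  skip_if(!nzchar(cli), "CLI script not installed")
  has_optparse <- requireNamespace("optparse", quietly = TRUE)
  skip_if(!has_optparse, "optparse not available")
  dir <- withr::local_tempdir()
  simdir <- file.path(dir, "sim"); outdir <- file.path(dir, "out")
  r1 <- system2("Rscript", c(cli, "simulate", "--out-dir", simdir, "--days", "1",
                             "--duration-min", "5", "--seed", "4"),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(r1, "status"), NULL)
  expect_true(file.exists(file.path(simdir, "day01.txt")))
  r2 <- system2("Rscript", c(cli, "analyze", "--raw", file.path(simdir, "day01.txt"),
                             "--calibration", file.path(simdir, "calibration.csv"),
                             "--out-dir", outdir),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(r2, "status"), NULL)
  expect_true(file.exists(file.path(outdir, "minutes.csv")))
  # missing input exits nonzero
  r3 <- suppressWarnings(
    system2("Rscript", c(cli, "analyze", "--raw", "nope.txt",
                         "--calibration", "nope.csv", "--out-dir", outdir),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(r3, "status"), 2)
})
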