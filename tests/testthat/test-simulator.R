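test_that("load distribution honours vertex, centroid and conservation", {
  g <- rig_geometry()
  # full mass on the cell it sits over
  for (i in 1:3) {
    l <- distribute_load(g$cells[i, ], 80, g)
    expect_equal(unname(l[i]), 80, tolerance = 1e-10)
    expect_equal(unname(sum(l)), 80, tolerance = 1e-10)
  }
  centroid <- colMeans(g$cells)
  expect_equal(unname(distribute_load(centroid, 90, g)), rep(30, 3), tolerance = 1e-10)
})

test_that("off-triangle loads go negative while the sum stays exact", {
  g <- rig_geometry()
  corner <- distribute_load(c(0, 0), 60, g)     # plate corner, outside the triangle
  expect_equal(unname(sum(corner)), 60, tolerance = 1e-10)
  expect_true(any(corner < 0))                  # the far cell is under tension
})

test_that("closed-form barycentric solve matches the 3x3 equilibrium oracle", {
  set.seed(17)
  g <- rig_geometry()
  for (i in 1:200) {
    p <- c(runif(1, -10, 70), runif(1, -10, 57))
    m <- runif(1, 1, 600)
    expect_equal(unname(distribute_load(p, m, g)), oracle_distribute(p, m, g),
                 tolerance = 1e-9)
  }
  expect_error(rig_geometry(cells = rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("cage geometry reproduces the published worked values", {
  small <- cage_geometry(28.3, 17.5, 10)
  expect_lt(abs(small$floor_area_cm2 - 495.3), 0.051)
  expect_lt(abs(small$fapa_cm2 - 49.5), 0.051)
  expect_lt(abs(small$radius_cm - 3.97), 0.005)
  large <- cage_geometry(57, 47, 10)
  expect_equal(large$fapa_cm2, 267.9)
  expect_lt(abs(sqrt(large$fapa_cm2 / pi) - 9.24), 0.006)
  unit <- cage_geometry(10, 10, 1)
  expect_equal(unit$floor_area_cm2, 100)
  expect_equal(unit$radius_cm, sqrt(100 / pi))
  expect_error(cage_geometry(10, 10, 0), ">= 1")
  expect_error(cage_geometry(-1, 10, 2), "positive")
})

test_that("zero activity, jitter and noise produce constant signals and zero SPA", {
  cfg <- simulation_config(n_days = 1, duration_min = 5, sigma_dark = 0,
                           sigma_light = 0, jitter_frac = 0, outlier_rate = 0,
                           daily_bias_g = 0, walk_cm_per_g = 0, seed = 2)
  sim <- simulate_raw(cfg)
  st <- sim$streams[[1]]
  expect_equal(length(unique(st$s1)), 1L)
  expect_equal(diff(st$t_us), rep(25000, nrow(st) - 1))
  fit <- spa_analyze(sim)
  expect_equal(fit$minutes$mwc, rep(0, 5))
  expect_equal(fit$minutes$swc, rep(0, 5))
})

test_that("simulation is reproducible from its seed and restores the RNG state", {
  cfg <- simulation_config(n_days = 1, duration_min = 2, seed = 99)
  set.seed(1234)
  before <- .Random.seed
  sim1 <- simulate_raw(cfg)
  expect_identical(.Random.seed, before)         # caller's RNG untouched
  sim2 <- simulate_raw(cfg)
  expect_identical(sim1$streams[[1]], sim2$streams[[1]])
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_raw_stream(sim1$streams[[1]], f1)
  write_raw_stream(sim2$streams[[1]], f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical re-run

  sim3 <- simulate_raw(simulation_config(n_days = 1, duration_min = 2, seed = 100))
  expect_false(identical(sim1$streams[[1]]$s1, sim3$streams[[1]]$s1))
})

test_that("ground truth carries the closed-form half-normal expectations", {
  cfg <- simulation_config(n_days = 3, duration_min = 5, sigma_dark = 24,
                           sigma_light = 8, daily_bias_g = 2, seed = 6)
  sim <- simulate_raw(cfg)
  k <- sqrt(2 / pi)
  expect_equal(sim$truth$days$expected_step_dark, sim$truth$days$bias_g + 24 * k)
  expect_equal(sim$truth$days$expected_step_light, sim$truth$days$bias_g + 8 * k)
  expect_true(all(sim$truth$days$bias_g >= 0 & sim$truth$days$bias_g <= 2))
  expect_equal(nrow(sim$truth$minutes), 3 * 5)
  expect_identical(sim$config$seed, 6L)
})

test_that("config validation flags unrealistic or invalid parameters", {
  expect_warning(simulation_config(sigma_dark = 5, sigma_light = 10), "diurnal")
  expect_error(simulation_config(jitter_frac = 1.2), "jitter")
  expect_error(simulation_config(sigma_dark = -1), ">= 0")
})

test_that("phase-specific activity scales shape the simulated stream", {
  # 11:00 start: first minutes are dark; a light-phase block lies 8 h later.
  # Short blocks around the transition check the sigma switch end-to-end.
  cfg <- simulation_config(n_days = 1, duration_min = 600, sigma_dark = 30,
                           sigma_light = 10, daily_bias_g = 0, seed = 42)
  sim <- simulate_raw(cfg)
  fit <- spa_analyze(sim, outlier_k = NULL)
  m <- fit$minutes
  expect_setequal(unique(m$phase), c("dark", "light"))
  ratio <- mean(m$mwc[m$phase == "dark"]) / mean(m$mwc[m$phase == "light"])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})
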