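# One full-day simulated recording with a 3:1 dark:light activity contrast,
# shared by the parameter-recovery and domain-localization checks (computed
# once per test run).
.recovery <- new.env(parent = emptyenv())

recovery_fit <- function() {
  if (is.null(.recovery$fit)) {
    cfg <- simulation_config(n_days = 1, sigma_dark = 30, sigma_light = 10,
                             daily_bias_g = 0, seed = 1)
    .recovery$sim <- simulate_raw(cfg)
    .recovery$fit <- spa_analyze(.recovery$sim)
  }
  .recovery$fit
}
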