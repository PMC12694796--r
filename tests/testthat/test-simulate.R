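test_that("config validation catches out-of-domain parameters", {
  expect_error(series_config("T", 20, ar1_phi = 1), "ar1_phi")
  expect_error(series_config("T", 20, diurnal_phase_h = 24), "diurnal_phase_h")
  expect_error(series_config("T", 20, n_days = 1), "n_days")
  expect_error(series_config("T", 20, noise_sd = -1), "non-negative")
  expect_error(series_config("T", 20, exceed_duration_h = 0), "exceed_duration_h")
})

test_that("a noiseless flat config yields a constant series at baseline", {
  s <- simulate_series(series_config("T", 20, n_days = 3, seed = 1))
  expect_equal(nrow(s), 72)
  expect_true(all(s$value == 20))
  expect_equal(diff(as.numeric(s$timestamp)), rep(3600, 71))
})

test_that("the same seed reproduces the series exactly; seeds differ otherwise", {
  cfg <- series_config("RH", 55, diurnal_amplitude = 3, noise_sd = 1.5,
                       exceed_rate_per_day = 1, exceed_magnitude = 10,
                       exceed_duration_h = 4, n_days = 10, seed = 99)
  expect_identical(simulate_series(cfg), simulate_series(cfg))
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(simulate_series(cfg), simulate_series(cfg2)))
})

test_that("a pure periodic signal has identical days: zero oscillation, exact mean", {
  cfg <- series_config("T", 20, diurnal_amplitude = 2, noise_sd = 0,
                       n_days = 6, seed = 5)
  s <- simulate_series(cfg)
  st <- series_stats(s, range_spec_t())
  expect_equal(st$osc_sum, 0)
  expect_equal(st$mean, 20, tolerance = 1e-9)
})

test_that("a day-to-day step of s contributes 24*|s| per day pair", {
  step <- 0.5
  cfg <- series_config("T", 20, seasonal_drift_per_day = step, noise_sd = 0,
                       diurnal_amplitude = 1.3, n_days = 5, seed = 2)
  st <- series_stats(simulate_series(cfg), range_spec_t())
  expect_equal(st$osc_sum, 24 * step * 4)
  expect_equal(st$osc_max, step)
})

test_that("campaign simulation builds one dataset per room and validates configs", {
  cfgs <- list(
    A = list(series_config("T", 20, n_days = 3, seed = 1),
             series_config("RH", 50, n_days = 3, seed = 2)),
    B = list(series_config("T", 18, n_days = 3, seed = 3)))
  camp <- simulate_campaign(cfgs)
  expect_named(camp, c("A", "B"))
  expect_named(camp$A$series, c("T", "RH"))
  expect_equal(unique(camp$B$series$T$room), "B")
  expect_error(simulate_campaign(list(A = list())), "no indicators")
  dup <- list(A = list(series_config("T", 20, n_days = 3, seed = 1),
                       series_config("T", 21, n_days = 3, seed = 2)))
  expect_error(simulate_campaign(dup), "duplicate indicator")
  expect_error(simulate_campaign(list()), "at least one room")
})

test_that("clean in-range simulations score near zero; pulses raise the risk", {
  # zero drift, baseline at the range midpoint: |mean score| bounded by noise
  noise_sd <- 0.3
  spec <- range_spec_t()
  cfg <- series_config("T", 20, diurnal_amplitude = 1, noise_sd = noise_sd,
                       n_days = 20, seed = 77)
  st <- series_stats(simulate_series(cfg), spec)
  expect_lt(abs(hmr_env_range(st, spec)), 2 * noise_sd / (24 - 16))

  # a compliant threshold series scores exactly 0
  co2 <- default_standards()[["CO2"]]
  clean <- series_config("CO2", 500, diurnal_amplitude = 40, noise_sd = 20,
                         n_days = 20, seed = 78)
  stc <- series_stats(simulate_series(clean), co2)
  expect_equal(hmr_env_threshold(stc, co2), 0)

  # nested exceedance pulses (shared seed) raise the semantic score monotonically
  rates <- c(0, 0.5, 1, 2, 4)
  scores <- vapply(rates, function(r) {
    cfg <- series_config("CO2", 900, diurnal_amplitude = 30, noise_sd = 15,
                         exceed_rate_per_day = r, exceed_magnitude = 400,
                         exceed_duration_h = 3, n_days = 30, seed = 500)
    hmr_env_threshold(series_stats(simulate_series(cfg), co2), co2)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_gt(scores[length(scores)], scores[1])
})

test_that("the demo campaign is assessable end to end", {
  camp <- demo_campaign(n_days = 8)
  expect_length(camp, 2)
  expect_equal(camp[["EH1-2"]]$area_m2, 78.7)
  expect_equal(camp[["EH3"]]$volume_m3, 175)
  a <- assess_campaign(camp)
  expect_equal(nrow(a$overall), 2)
})
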