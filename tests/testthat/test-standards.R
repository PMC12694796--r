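test_that("packaged default registry carries the recommended limits", {
  std <- default_standards()
  expect_setequal(names(std),
                  c("T", "RH", "AL", "CO2", "HCHO", "TVOC", "PM2.5", "PM10", "I+", "I-"))
  expect_equal(std[["T"]]$low, 16)
  expect_equal(std[["T"]]$high, 24)
  expect_equal(std[["T"]]$mode, "range")
  expect_equal(std[["RH"]][c("low", "high")], list(low = 45, high = 60))
  expect_equal(std[["AL"]][c("low", "high")], list(low = 50, high = 200))
  expect_equal(std[["HCHO"]]$high, 0.04)
  expect_equal(std[["HCHO"]]$mode, "upper_threshold")
  expect_equal(std[["CO2"]]$high, 1000)
  expect_equal(std[["TVOC"]]$high, 1)
  expect_equal(std[["PM2.5"]]$high, 35)
  expect_equal(std[["PM10"]]$high, 35)
  expect_equal(std[["I+"]]$high, 1000)
  expect_equal(std[["I-"]]$mode, "lower_threshold")
  expect_equal(std[["I-"]]$low, 1000)
})

test_that("spec validation rejects malformed standards", {
  expect_error(indicator_spec("RH", "%", "range", low = 60, high = 45,
                              osc_low = 3, osc_high = 10),
               "below high")
  expect_error(indicator_spec("X", "u", "upper_threshold", low = 1,
                              osc_low = 1, osc_high = 2),
               "needs high")
  expect_error(indicator_spec("X", "u", "lower_threshold", high = 1,
                              osc_low = 1, osc_high = 2),
               "needs low")
  expect_error(indicator_spec("T", "degC", "range", low = 16, high = 24,
                              osc_low = 2, osc_high = 1),
               "osc_high")
  expect_error(indicator_spec("T", "degC", "range", low = 16, high = 24,
                              osc_fraction = -0.1, osc_low = 1, osc_high = 2),
               "non-negative")
  # duplicate indicator in a document
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(indicators = list(
    list(name = "T", mode = "range", low = 16, high = 24, osc_low = 1, osc_high = 2),
    list(name = "T", mode = "range", low = 10, high = 20, osc_low = 1, osc_high = 2))), f)
  expect_error(load_standards(f), "duplicate indicator")
})

test_that("effective bounds widen multiplicatively and are monotone in the fraction", {
  s0 <- range_spec_t(osc_fraction = 0)
  expect_equal(unname(effective_bounds(s0)), c(16, 24))
  s5 <- range_spec_t(osc_fraction = 0.05)
  expect_equal(unname(effective_bounds(s5)), c(15.2, 25.2))
  rh <- indicator_spec("RH", "%", "range", low = 45, high = 60,
                       osc_fraction = 0.03, osc_low = 3, osc_high = 10)
  expect_equal(unname(effective_bounds(rh)), c(43.65, 61.8))
  # monotone widening
  fr <- seq(0, 0.2, by = 0.02)
  bounds <- vapply(fr, function(f) effective_bounds(range_spec_t(osc_fraction = f)),
                   numeric(2))
  expect_true(all(diff(bounds["high", ]) > 0))
  expect_true(all(diff(bounds["low", ]) < 0))
  expect_error(effective_bounds(default_standards()[["CO2"]]), "range-mode")
})

test_that("standards round-trip through the YAML document format", {
  std <- default_standards()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_standards(std, f)
  expect_equal(load_standards(f), std)
  # JSON dialect is accepted too
  j <- withr::local_tempfile(fileext = ".json")
  entries <- lapply(unname(std), function(s) {
    s <- unclass(s); s[!vapply(s, is.null, logical(1))]
  })
  jsonlite::write_json(list(indicators = entries), j, auto_unbox = TRUE, digits = NA)
  expect_equal(load_standards(j), std)
})

test_that("threshold saturation defaults to twice (half) the limit", {
  std <- default_standards()
  expect_equal(hmrisk:::threshold_saturation(std[["HCHO"]]), 0.08)
  bare <- indicator_spec("CO2", "ppm", "upper_threshold", high = 1000,
                         osc_low = 50, osc_high = 200)
  expect_equal(hmrisk:::threshold_saturation(bare), 2000)
  bare_lo <- indicator_spec("I-", "ions/cm3", "lower_threshold", low = 1000,
                            osc_low = 100, osc_high = 500)
  expect_equal(hmrisk:::threshold_saturation(bare_lo), 500)
  bad <- indicator_spec("CO2", "ppm", "upper_threshold", high = 1000,
                        osc_low = 50, osc_high = 200, saturation = 800)
  expect_error(hmrisk:::threshold_saturation(bad), "must exceed the threshold")
})
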