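stats_with <- function(mean = 20, exceed_high = 0, exceed_low = 0,
                       osc_mean = 0, osc_max = 0, n = 100) {
  structure(list(mean = mean, n = n, exceed_fraction_high = exceed_high,
                 exceed_fraction_low = exceed_low, osc_sum = osc_mean * n,
                 osc_mean = osc_mean, osc_max = osc_max, n_pairs = n),
            class = "series_stats")
}

test_that("range mean score is affine between the bounds with 0/+1/-1 anchors", {
  spec <- range_spec_t()
  expect_equal(hmr_env_range(stats_with(mean = 20), spec), 0)
  expect_equal(hmr_env_range(stats_with(mean = 24), spec), 1)
  expect_equal(hmr_env_range(stats_with(mean = 16), spec), -1)
  # linear map of the observed period mean
  expect_equal(hmr_env_range(stats_with(mean = 19.9), spec), -0.025)
  # affine in the mean between the bounds
  means <- seq(16, 24, length.out = 9)
  scores <- vapply(means, function(m) hmr_env_range(stats_with(mean = m), spec),
                   numeric(1))
  expect_equal(scores, seq(-1, 1, length.out = 9))
  # clamped outside
  expect_equal(hmr_env_range(stats_with(mean = 40), spec), 1)
  expect_equal(hmr_env_range(stats_with(mean = 0), spec), -1)
  degenerate <- spec; degenerate$low <- 24
  expect_error(hmr_env_range(stats_with(), degenerate), "degenerate")
})

test_that("exceedance_only range mode scores 0 inside and grows outside", {
  spec <- range_spec_t()
  expect_equal(hmr_env_range(stats_with(mean = 20), spec, mode = "exceedance_only"), 0)
  expect_equal(hmr_env_range(stats_with(mean = 23.9), spec, mode = "exceedance_only"), 0)
  hi <- hmr_env_range(stats_with(mean = 26, exceed_high = 0.6), spec,
                      mode = "exceedance_only")
  expect_gt(hi, 0)
  lo <- hmr_env_range(stats_with(mean = 14, exceed_low = 0.6), spec,
                      mode = "exceedance_only")
  expect_lt(lo, 0)
  expect_equal(hi, -lo)  # mirrored axes
})

test_that("range oscillation score anchors at the allowed-oscillation band", {
  spec <- range_spec_t()  # band 1..2
  expect_equal(hmr_osc_range(stats_with(osc_mean = 1.5), spec), 0)
  expect_equal(hmr_osc_range(stats_with(osc_mean = 2), spec), 1)
  expect_equal(hmr_osc_range(stats_with(osc_mean = 1), spec), -1)
  expect_equal(hmr_osc_range(stats_with(osc_mean = 10), spec), 1)  # clamped
  expect_error(hmr_osc_range(stats_with(), default_standards()[["CO2"]]),
               "range-mode")
})

test_that("semantic threshold score is 0 under the limit and saturates at 1", {
  hcho <- default_standards()[["HCHO"]]
  expect_equal(hmr_env_threshold(stats_with(mean = 0.02, exceed_high = 0), hcho), 0)
  expect_equal(hmr_env_threshold(stats_with(mean = 0.08, exceed_high = 1), hcho), 1)
  # hand-evaluated mixture: E_mag = (0.07-0.04)/(0.08-0.04) = 0.75, E_freq = 0.717
  expect_equal(hmr_env_threshold(stats_with(mean = 0.07, exceed_high = 0.717), hcho),
               0.5 * 0.75 + 0.5 * 0.717)
  # verbatim linear form: 0 below the threshold, then the printed map clamped to [0, 1]
  expect_equal(hmr_env_threshold(stats_with(mean = 0.02), hcho, mode = "verbatim"), 0)
  expect_equal(hmr_env_threshold(stats_with(mean = 0.05, exceed_high = 0.5), hcho,
                                 mode = "verbatim"), 0.5)
})

test_that("semantic threshold score is monotone in frequency and magnitude", {
  hcho <- default_standards()[["HCHO"]]
  freqs <- seq(0, 1, by = 0.1)
  by_freq <- vapply(freqs, function(f)
    hmr_env_threshold(stats_with(mean = 0.05, exceed_high = f), hcho), numeric(1))
  expect_true(all(diff(by_freq) >= 0))
  means <- seq(0.041, 0.1, length.out = 10)
  by_mag <- vapply(means, function(m)
    hmr_env_threshold(stats_with(mean = m, exceed_high = 0.5), hcho), numeric(1))
  expect_true(all(diff(by_mag) >= 0))
})

test_that("lower-threshold risk mirrors onto the deficit axis", {
  im <- default_standards()[["I-"]]  # limit 1000, saturation 500
  expect_equal(hmr_env_threshold(stats_with(mean = 1200, exceed_low = 0), im), 0)
  expect_equal(hmr_env_threshold(stats_with(mean = 500, exceed_low = 1), im), 1)
  mid <- hmr_env_threshold(stats_with(mean = 750, exceed_low = 0.5), im)
  expect_equal(mid, 0.5)
})

test_that("threshold oscillation score locates the mean between floor and worst", {
  co2 <- default_standards()[["CO2"]]  # osc floor 50
  expect_equal(hmr_osc_threshold(stats_with(osc_mean = 0, osc_max = 0), co2), 0)
  expect_equal(hmr_osc_threshold(stats_with(osc_mean = 200, osc_max = 200), co2), 1)
  expect_equal(hmr_osc_threshold(stats_with(osc_mean = 125, osc_max = 200), co2), 0.5)
  # degenerate: no variation beyond the safe floor
  expect_equal(hmr_osc_threshold(stats_with(osc_mean = 50, osc_max = 50), co2), 0)
  # verbatim form saturates at osc_mean == osc_max too
  expect_equal(hmr_osc_threshold(stats_with(osc_mean = 200, osc_max = 200), co2,
                                 mode = "verbatim"), 1)
})

test_that("combined index is the exact mean of its components", {
  expect_equal(hmr_combine(0.56, 0.88), 0.72)
  expect_equal(hmr_combine(0, 0), 0)
  expect_equal(hmr_combine(-1, 1), 0)
  expect_error(hmr_combine(NA_real_, 0), "finite")
})

test_that("risk bands follow the |score| cut-points with direction qualifiers", {
  expect_equal(classify_risk(0.4, "hmr_e"), "moderate")
  expect_equal(classify_risk(0.128, "hmr_h"), "low")
  expect_equal(classify_risk(-1, "hmr_e", direction = TRUE), "high/deficit")
  expect_equal(classify_risk(0.7, "hmr_e", direction = TRUE), "high/excess")
  expect_equal(classify_risk(c(0.1, -0.3, 0.95), "hmr_e"),
               c("low", "moderate", "high"))
  expect_error(classify_risk(-0.2, "hmr_h"), "domain")
  expect_error(classify_risk(1.5, "hmr_e"), "domain")
})
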