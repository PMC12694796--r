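#' Configuration for one synthetic hourly series
#'
#' Describes the generative model of [simulate_series()]:
#' `value(t) = baseline + diurnal_amplitude * sin(2*pi*(hour - diurnal_phase_h)/24)
#'  + seasonal_drift_per_day * day + AR(1) noise + exceedance pulses`.
#' The AR(1) term has autoregression `ar1_phi` and innovation standard
#' deviation `noise_sd` (hourly indoor readings are strongly autocorrelated,
#' hence the default `phi = 0.8`). Exceedance events arrive as additive
#' boxcar pulses: each starts with probability `exceed_rate_per_day / 24`
#' per hour and adds `exceed_magnitude` for `exceed_duration_h` hours
#' (overlapping pulses stack).
#'
#' @param indicator Indicator identifier.
#' @param baseline Long-run level, in the indicator's units.
#' @param diurnal_amplitude Amplitude of the 24-h sinusoid (>= 0).
#' @param diurnal_phase_h Phase of the sinusoid in hours, in \[0, 24).
#' @param seasonal_drift_per_day Linear trend per day.
#' @param ar1_phi AR(1) coefficient in \[0, 1).
#' @param noise_sd Innovation standard deviation (>= 0).
#' @param exceed_rate_per_day Expected number of pulse starts per day (>= 0).
#' @param exceed_magnitude Additive pulse height (>= 0).
#' @param exceed_duration_h Pulse length in hours (>= 1).
#' @param n_days Number of simulated days (>= 2).
#' @param seed Integer seed; the series is fully determined by it.
#' @return A validated list of class `synthetic_series_config`.
#' @export
series_config <- function(indicator, baseline, diurnal_amplitude = 0,
                          diurnal_phase_h = 0, seasonal_drift_per_day = 0,
                          ar1_phi = 0.8, noise_sd = 0,
                          exceed_rate_per_day = 0, exceed_magnitude = 0,
                          exceed_duration_h = 1, n_days = 2, seed = 1) {
  cfg <- list(indicator = as.character(indicator), baseline = baseline,
              diurnal_amplitude = diurnal_amplitude,
              diurnal_phase_h = diurnal_phase_h,
              seasonal_drift_per_day = seasonal_drift_per_day,
              ar1_phi = ar1_phi, noise_sd = noise_sd,
              exceed_rate_per_day = exceed_rate_per_day,
              exceed_magnitude = exceed_magnitude,
              exceed_duration_h = as.integer(exceed_duration_h),
              n_days = as.integer(n_days), seed = as.integer(seed))
  nums <- unlist(cfg[-1])
  if (any(!is.finite(nums))) stopf("series_config: all fields must be finite")
  if (cfg$diurnal_amplitude < 0 || cfg$noise_sd < 0 ||
      cfg$exceed_rate_per_day < 0 || cfg$exceed_magnitude < 0) {
    stopf("series_config: amplitudes, noise and exceedance parameters must be non-negative")
  }
  if (cfg$diurnal_phase_h < 0 || cfg$diurnal_phase_h >= 24) {
    stopf("series_config: diurnal_phase_h must lie in [0, 24)")
  }
  if (cfg$ar1_phi < 0 || cfg$ar1_phi >= 1) stopf("series_config: ar1_phi must lie in [0, 1)")
  if (cfg$exceed_duration_h < 1) stopf("series_config: exceed_duration_h must be >= 1")
  if (cfg$n_days < 2) stopf("series_config: n_days must be >= 2 (day pairs are needed)")
  structure(cfg, class = "synthetic_series_config")
}

#' Simulate one hourly indicator series
#'
#' Generates `n_days * 24` hourly values under the model described in
#' [series_config()], starting at `start` (midnight). The same config (and
#' seed) always yields the identical series.
#'
#' @param config A `synthetic_series_config`.
#' @param room Room identifier stamped on the series.
#' @param unit Unit string stamped on the series.
#' @param start First timestamp (midnight of day 0).
#' @return A tibble with `timestamp`, `room`, `sensor_id`, `indicator`,
#'   `value`, `unit` (sensor_id `"synthetic"`).
#' @export
simulate_series <- function(config, room = "room1", unit = "",
                            start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(config, "synthetic_series_config"))
  n <- config$n_days * 24L
  hour <- rep(0:23, config$n_days)
  day <- rep(seq_len(config$n_days) - 1L, each = 24L)
  deterministic <- config$baseline +
    config$diurnal_amplitude * sin(2 * pi * (hour - config$diurnal_phase_h) / 24) +
    config$seasonal_drift_per_day * day

  with_seed(config$seed, {
    if (config$noise_sd > 0) {
      innov <- stats::rnorm(n, 0, config$noise_sd)
      ar <- numeric(n)
      ar[1] <- stats::rnorm(1, 0, config$noise_sd / sqrt(1 - config$ar1_phi^2))
      for (t in 2:n) ar[t] <- config$ar1_phi * ar[t - 1] + innov[t]
    } else {
      ar <- numeric(n)
    }
    pulse <- numeric(n)
    if (config$exceed_rate_per_day > 0 && config$exceed_magnitude > 0) {
      starts <- which(stats::runif(n) < config$exceed_rate_per_day / 24)
      for (s in starts) {
        idx <- s:min(n, s + config$exceed_duration_h - 1L)
        pulse[idx] <- pulse[idx] + config$exceed_magnitude
      }
    }
    tibble::tibble(
      timestamp = start + 3600 * (seq_len(n) - 1L),
      room = room, sensor_id = "synthetic", indicator = config$indicator,
      value = deterministic + ar + pulse, unit = unit)
  })
}

#' Simulate a multi-room monitoring campaign
#'
#' @param room_configs Named list: room identifier -> list of
#'   `synthetic_series_config` objects, one per indicator.
#' @param metadata Optional named list: room -> list(area_m2, volume_m3).
#' @param start First timestamp, passed to [simulate_series()].
#' @return A list of [room_dataset()] objects, one per room.
#' @export
simulate_campaign <- function(room_configs, metadata = NULL,
                              start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  if (length(room_configs) == 0) stopf("simulate_campaign: at least one room required")
  if (is.null(names(room_configs)) || any(!nzchar(names(room_configs)))) {
    stopf("simulate_campaign: room_configs must be a named list")
  }
  lapply(stats::setNames(names(room_configs), names(room_configs)), function(room) {
    cfgs <- room_configs[[room]]
    if (length(cfgs) == 0) stopf("room '%s': no indicators configured", room)
    inds <- vapply(cfgs, `[[`, character(1), "indicator")
    if (anyDuplicated(inds)) stopf("room '%s': duplicate indicator in configs", room)
    series <- lapply(cfgs, simulate_series, room = room, start = start)
    meta <- metadata[[room]] %||% list()
    room_dataset(room, stats::setNames(series, inds),
                 area_m2 = meta$area_m2 %||% NA_real_,
                 volume_m3 = meta$volume_m3 %||% NA_real_)
  })
}

#' Packaged demonstration campaign
#'
#' A two-room synthetic campaign emulating an eight-month (default 240-day)
#' hourly monitoring of the ten standard indicators in two exhibition halls
#' of a museum without natural ventilation. Baselines, diurnal amplitudes
#' and noise levels are set so the marginal means and spreads resemble
#' realistic exhibition-hall conditions: temperature near 19-20 degC,
#' relative humidity running above its 60 % limit, formaldehyde frequently
#' above 0.04 mg/m3, positive ions oversaturated, the remaining pollutants
#' comfortably compliant.
#'
#' @param n_days Campaign length in days.
#' @param seed Integer seed; per-series seeds are derived from it.
#' @return A list of two [room_dataset()] objects (`"EH1-2"`, `"EH3"`).
#' @export
demo_campaign <- function(n_days = 240, seed = 20240101) {
  base <- list(
    # name, baseline by room, amplitude, drift/day, noise sd, pulse rate/day, magnitude, duration
    list("T",     c(19.9, 19.4), 0.8,  0.004, 0.35, 0,    0,    1),
    list("RH",    c(60.8, 63.9), 2.0,  0.010, 1.80, 0,    0,    1),
    list("AL",    c(70.5, 73.0), 40.0, 0,     12.0, 0.3,  120,  2),
    list("CO2",   c(493, 519),   30.0, 0,     18.0, 0.05, 600,  2),
    list("HCHO",  c(0.055, 0.045), 0.012, 0,  0.008, 0.2, 0.06, 3),
    list("TVOC",  c(0.52, 0.59), 0.03, 0,     0.015, 0,   0,    1),
    list("PM2.5", c(15.5, 15.7), 2.0,  0,     1.5,  0,    0,    1),
    list("PM10",  c(20.4, 21.3), 2.5,  0,     1.8,  0,    0,    1),
    list("I+",    c(1380, 1482), 150,  0,     180,  0,    0,    1),
    list("I-",    c(960, 1154),  150,  0,     200,  0,    0,    1))
  rooms <- c("EH1-2", "EH3")
  cfgs <- lapply(seq_along(rooms), function(r) {
    lapply(seq_along(base), function(i) {
      p <- base[[i]]
      series_config(indicator = p[[1]], baseline = p[[2]][r],
                    diurnal_amplitude = p[[3]], diurnal_phase_h = 15,
                    seasonal_drift_per_day = p[[4]], ar1_phi = 0.8,
                    noise_sd = p[[5]], exceed_rate_per_day = p[[6]],
                    exceed_magnitude = p[[7]], exceed_duration_h = p[[8]],
                    n_days = n_days,
                    seed = (seed + 1000L * r + i) %% .Machine$integer.max)
    })
  })
  names(cfgs) <- rooms
  simulate_campaign(cfgs, metadata = list(
    `EH1-2` = list(area_m2 = 78.7, volume_m3 = 370),
    EH3 = list(area_m2 = 37.2, volume_m3 = 175)))
}

# Flatten room datasets into one long hmr_ts tibble (e.g. for CSV export).
campaign_to_ts <- function(datasets) {
  out <- dplyr::bind_rows(lapply(datasets, function(ds) dplyr::bind_rows(ds$series)))
  class(out) <- c("hmr_ts", class(out))
  out
}
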