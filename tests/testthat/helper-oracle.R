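# Test fixtures are built in code; no data files.

# Hourly series starting at midnight from a plain numeric vector (NA = gap).
make_hourly_series <- function(values, indicator = "T", room = "R1",
                               start = as.POSIXct("2024-03-01 00:00:00", tz = "UTC")) {
  tibble::tibble(
    timestamp = start + 3600 * (seq_along(values) - 1L),
    room = room, sensor_id = "s1", indicator = indicator,
    value = as.numeric(values), unit = "")
}

# Independent brute-force oracle for the day-to-day oscillation statistics:
# an explicit double loop over (day pair, hour) against a hash-map lookup,
# written before and kept independent of the implementation under test.
osc_bruteforce <- function(series) {
  obs <- series[!is.na(series$value), ]
  env <- new.env(hash = TRUE)
  day <- format(obs$timestamp, "%Y-%m-%d")
  hour <- format(obs$timestamp, "%H")
  for (i in seq_len(nrow(obs))) {
    assign(paste(day[i], hour[i]), obs$value[i], envir = env)
  }
  days <- seq(as.Date(min(day)), as.Date(max(day)), by = "day")
  diffs <- numeric(0)
  for (k in seq_len(length(days) - 1L)) {
    for (j in 0:23) {
      h <- sprintf("%02d", j)
      a <- get0(paste(as.character(days[k]), h), envir = env)
      b <- get0(paste(as.character(days[k + 1L]), h), envir = env)
      if (!is.null(a) && !is.null(b)) diffs <- c(diffs, abs(a - b))
    }
  }
  list(osc_sum = sum(diffs), osc_max = if (length(diffs)) max(diffs) else 0,
       n_pairs = length(diffs))
}

# Random hourly series with gaps, for property tests.
random_series <- function(n_days, missing_frac = 0.1) {
  n <- n_days * 24L
  v <- stats::rnorm(n, 20, 5)
  v[stats::runif(n) < missing_frac] <- NA
  make_hourly_series(v)
}

range_spec_t <- function(...) {
  indicator_spec("T", "degC", "range", low = 16, high = 24,
                 osc_low = 1, osc_high = 2, ...)
}
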