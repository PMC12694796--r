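#' Summary statistics feeding the risk scores
#'
#' Reduces one hourly series to the quantities the index formulas consume:
#' the period mean, the number of observations, the fractions of observations
#' beyond the applicable limits, and the day-to-day oscillation statistics.
#'
#' The oscillation sum pairs each hour of day *k* with the same hour of day
#' *k + 1* and accumulates absolute differences:
#' `osc_sum = sum over k, j of |X(day k, hour j) - X(day k+1, hour j)|`.
#' Pairs where either value is missing are skipped; only consecutive calendar
#' days form pairs. `osc_mean` divides `osc_sum` by the number of differences
#' actually summed (`n_pairs`), and `osc_max` is the largest single absolute
#' difference (0 when no pair exists).
#'
#' @param series A tibble of hourly observations for one (room, indicator)
#'   pair (columns `timestamp`, `value`; NA values are treated as missing).
#' @param spec The `indicator_spec` providing the limits for the exceedance
#'   fractions (range limits are widened by `osc_fraction` first).
#' @return A list of class `series_stats` with `mean`, `n`,
#'   `exceed_fraction_high`, `exceed_fraction_low`, `osc_sum`, `osc_mean`,
#'   `osc_max`, `n_pairs`.
#' @export
series_stats <- function(series, spec) {
  stopifnot(inherits(spec, "indicator_spec"))
  obs <- series[!is.na(series$value), ]
  if (nrow(obs) == 0) stopf("series_stats(): empty series for '%s'", spec$name)
  v <- obs$value
  n <- length(v)

  if (spec$mode == "range") {
    b <- effective_bounds(spec)
    ex_hi <- mean(v > b[["high"]])
    ex_lo <- mean(v < b[["low"]])
  } else if (spec$mode == "upper_threshold") {
    ex_hi <- mean(v > spec$high)
    ex_lo <- 0
  } else {
    ex_hi <- 0
    ex_lo <- mean(v < spec$low)
  }

  # day x hour matrix on the full calendar grid, then first differences
  # down the day axis
  day <- as.Date(format(obs$timestamp, "%Y-%m-%d"))
  hour <- as.integer(format(obs$timestamp, "%H"))
  days <- seq(min(day), max(day), by = "day")
  m <- matrix(NA_real_, nrow = length(days), ncol = 24,
              dimnames = list(as.character(days), 0:23))
  m[cbind(match(day, days), hour + 1L)] <- v
  if (length(days) >= 2) {
    d <- abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
    # enumerate in the order the sum is defined: day pairs outer, hours inner
    d <- as.vector(t(d))
    d <- d[!is.na(d)]
  } else {
    d <- numeric(0)
  }

  structure(list(
    mean = mean(v), n = n,
    exceed_fraction_high = ex_hi, exceed_fraction_low = ex_lo,
    osc_sum = sum(d), osc_mean = if (length(d)) mean(d) else 0,
    osc_max = if (length(d)) max(d) else 0, n_pairs = length(d)),
    class = "series_stats")
}

#' @export
print.series_stats <- function(x, ...) {
  cat(sprintf(paste0("<series_stats> n = %d, mean = %.4g, exceed high/low = %.3f/%.3f,\n",
                     "  osc: sum = %.4g, mean = %.4g, max = %.4g over %d day pairs\n"),
              x$n, x$mean, x$exceed_fraction_high, x$exceed_fraction_low,
              x$osc_sum, x$osc_mean, x$osc_max, x$n_pairs))
  invisible(x)
}
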