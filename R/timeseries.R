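#' Read hourly sensor time series from CSV
#'
#' The expected layout is one record per observation with header
#' `timestamp,room,sensor_id,indicator,value,unit` and ISO-8601 timestamps
#' (`YYYY-MM-DD HH:MM` or with a `T` separator). Timestamps are treated as
#' local wall-clock hours; no time-zone arithmetic is applied.
#'
#' @param path CSV file path.
#' @param standards Optional `standards_registry`; when supplied, units are
#'   checked against it and unknown indicators raise a warning (the rows are
#'   still returned).
#' @return A tibble of class `hmr_ts` with columns `timestamp` (POSIXct),
#'   `room`, `sensor_id`, `indicator`, `value`, `unit`, sorted by time within
#'   each (room, sensor, indicator) series.
#' @details Duplicated `(timestamp, room, sensor_id, indicator)` records are an
#'   error; a non-numeric value or unparseable timestamp is reported with its
#'   line number.
#' @seealso [write_timeseries()], [aggregate_room()], [qc_report()]
#' @export
read_timeseries <- function(path, standards = NULL) {
  if (!file.exists(path)) stopf("time-series file not found: %s", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("timestamp", "room", "sensor_id", "indicator", "value", "unit")
  if (!all(needed %in% names(raw))) {
    stopf("time-series CSV must have columns %s", paste(needed, collapse = ", "))
  }
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    idx <- is.na(ts)
    if (!any(idx)) break
    ts[idx] <- as.POSIXct(raw$timestamp[idx], tz = "UTC", format = f)
  }
  bad_ts <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad_ts)) {
    stopf("unparseable timestamp at data line(s): %s",
          paste(utils::head(bad_ts, 5), collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad_val <- which(is.na(val) & !is.na(raw$value) & raw$value != "NA")
  if (length(bad_val)) {
    stopf("non-numeric value at data line(s): %s",
          paste(utils::head(bad_val, 5), collapse = ", "))
  }
  out <- tibble::tibble(timestamp = ts, room = raw$room, sensor_id = raw$sensor_id,
                        indicator = raw$indicator, value = val, unit = raw$unit)
  dup <- duplicated(out[c("timestamp", "room", "sensor_id", "indicator")])
  if (any(dup)) {
    stopf("duplicated (timestamp, room, sensor_id, indicator) record at line(s): %s",
          paste(utils::head(which(dup), 5), collapse = ", "))
  }
  out <- dplyr::arrange(out, .data$room, .data$sensor_id, .data$indicator, .data$timestamp)
  if (!is.null(standards)) {
    unknown <- setdiff(unique(out$indicator), names(standards))
    if (length(unknown)) {
      warning(sprintf("indicator(s) not in standards registry: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  class(out) <- c("hmr_ts", class(out))
  out
}

#' Write hourly sensor time series to CSV
#'
#' Values are printed at full precision (up to 15 significant digits), so a
#' write/read round trip reproduces the numbers exactly.
#'
#' @param ts An `hmr_ts` tibble (see [read_timeseries()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  out <- tibble::tibble(
    timestamp = format(ts$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    room = ts$room, sensor_id = ts$sensor_id, indicator = ts$indicator,
    value = formatC(ts$value, format = "g", digits = 17), unit = ts$unit)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Aggregate multiple sensors into one room-level series
#'
#' Sensors covering the same room and indicator are combined by an unweighted
#' per-timestamp arithmetic mean over the sensors reporting at that hour;
#' hours covered by a single sensor keep that sensor's value. The result
#' carries `sensor_id = "aggregated"`. The operation is invariant to the
#' order of input rows and idempotent on an already-aggregated series.
#'
#' @param series A tibble of observations for exactly one (room, indicator)
#'   pair, possibly from several sensors.
#' @return A tibble with one row per timestamp, flagged aggregated.
#' @export
aggregate_room <- function(series) {
  if (is.null(series) || nrow(series) == 0) stopf("aggregate_room(): empty input")
  if (length(unique(series$room)) != 1 || length(unique(series$indicator)) != 1) {
    stopf("aggregate_room(): input must cover exactly one room and one indicator")
  }
  out <- series |>
    dplyr::group_by(.data$timestamp) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value)) |>
    dplyr::arrange(.data$timestamp)
  tibble::tibble(timestamp = out$timestamp, room = series$room[1],
                 sensor_id = "aggregated", indicator = series$indicator[1],
                 value = out$value, unit = series$unit[1])
}

# Aggregate a whole long table to one series per (room, indicator).
aggregate_all <- function(ts) {
  parts <- split(ts, interaction(ts$room, ts$indicator, drop = TRUE))
  dplyr::bind_rows(lapply(parts, aggregate_room))
}

#' Quality-control summary for one sensor series
#'
#' Reports coverage against the nominal hourly cadence between the first and
#' last observation: number of gaps (maximal runs of missing hours), the
#' longest gap in hours, the fraction of expected hours missing, and the
#' count of physically implausible values (negative readings for
#' non-temperature indicators; relative humidity outside 0-100).
#'
#' @param series A tibble of observations for one (room, indicator) pair.
#' @param spec Optional `indicator_spec` used to pick the plausibility rule
#'   (by default inferred from the indicator name).
#' @return A list with `n_obs`, `expected_hours`, `gap_count`, `longest_gap_h`,
#'   `fraction_missing`, `n_implausible`.
#' @export
qc_report <- function(series, spec = NULL) {
  if (nrow(series) == 0) {
    return(list(n_obs = 0L, expected_hours = 0L, gap_count = 0L,
                longest_gap_h = 0L, fraction_missing = NA_real_, n_implausible = 0L))
  }
  obs <- series[!is.na(series$value), ]
  hours <- seq(min(series$timestamp), max(series$timestamp), by = "hour")
  present <- hours %in% obs$timestamp
  runs <- rle(!present)
  gaps <- runs$lengths[runs$values]
  ind <- spec$name %||% series$indicator[1]
  v <- obs$value
  implausible <- if (identical(ind, "RH")) sum(v < 0 | v > 100)
                 else if (identical(ind, "T")) 0L
                 else sum(v < 0)
  list(n_obs = nrow(obs),
       expected_hours = length(hours),
       gap_count = length(gaps),
       longest_gap_h = if (length(gaps)) max(gaps) else 0L,
       fraction_missing = sum(!present) / length(hours),
       n_implausible = as.integer(implausible))
}

#' Bundle per-indicator series into a room dataset
#'
#' @param room Room identifier.
#' @param series Named list of per-indicator series tibbles (at most one per
#'   indicator; each is aggregated across sensors on construction if needed).
#' @param area_m2,volume_m3 Room metadata (optional, must be positive).
#' @return An object of class `room_dataset`.
#' @export
room_dataset <- function(room, series, area_m2 = NA_real_, volume_m3 = NA_real_) {
  if (length(series) == 0) stopf("room '%s': no indicator series", room)
  inds <- vapply(series, function(s) s$indicator[1], character(1))
  if (anyDuplicated(inds)) {
    stopf("room '%s': duplicate indicator series (%s)", room,
          paste(unique(inds[duplicated(inds)]), collapse = ", "))
  }
  names(series) <- inds
  if (!is.na(area_m2) && area_m2 <= 0) stopf("area_m2 must be positive")
  if (!is.na(volume_m3) && volume_m3 <= 0) stopf("volume_m3 must be positive")
  structure(list(room = room, area_m2 = area_m2, volume_m3 = volume_m3,
                 series = series), class = "room_dataset")
}

#' @export
print.room_dataset <- function(x, ...) {
  cat(sprintf("<room_dataset> %s: %d indicator series (%s)\n",
              x$room, length(x$series), paste(names(x$series), collapse = ", ")))
  invisible(x)
}
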