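#' Indicator standards
#'
#' Every score in the package is parameterised by a per-indicator standard: a
#' scoring mode (an acceptability *range* such as 16-24 degC for temperature,
#' or a one-sided *threshold* such as HCHO <= 0.04 mg/m3), the corresponding
#' limits, and the daily-oscillation allowances used by the oscillation
#' component. `indicator_spec()` builds and validates one such standard;
#' `load_standards()` reads a whole registry from YAML or JSON;
#' `default_standards()` returns the registry of internationally recommended
#' limits that ships with the package.
#'
#' @section Fields:
#' \describe{
#'   \item{name}{indicator identifier, e.g. `"T"`, `"RH"`, `"PM2.5"`.}
#'   \item{unit}{measurement unit, free text.}
#'   \item{mode}{`"range"`, `"upper_threshold"` or `"lower_threshold"`.}
#'   \item{low, high}{acceptability limits. A range needs both (`low < high`);
#'     an upper threshold needs `high` (the must-not-exceed limit); a lower
#'     threshold needs `low` (the must-not-fall-below limit).}
#'   \item{osc_fraction}{fractional widening of the range allowed by the
#'     standard before a value counts as out of bounds; `0` keeps the bare
#'     published limits (the default).}
#'   \item{osc_low, osc_high}{minimum and maximum allowed day-to-day
#'     oscillation of the indicator, in its own units (`osc_high > osc_low`).}
#'   \item{saturation}{for threshold indicators, the level at which the
#'     mean-exceedance term of the semantic score saturates at 1; defaults to
#'     twice the threshold (half, for a lower threshold).}
#'   \item{source}{citation text for the standard.}
#' }
#'
#' @param name,unit,mode,low,high,osc_fraction,osc_low,osc_high,saturation,source
#'   See section Fields.
#' @return An object of class `indicator_spec` (a named list).
#' @examples
#' t_spec <- indicator_spec("T", "degC", "range", low = 16, high = 24,
#'                          osc_low = 1, osc_high = 2)
#' effective_bounds(t_spec)
#' @export
indicator_spec <- function(name, unit = "", mode = c("range", "upper_threshold", "lower_threshold"),
                           low = NULL, high = NULL, osc_fraction = 0,
                           osc_low = 0, osc_high = NULL, saturation = NULL,
                           source = "") {
  mode <- match.arg(mode)
  spec <- structure(
    list(name = as.character(name), unit = as.character(unit), mode = mode,
         low = if (!is.null(low)) as.numeric(low), high = if (!is.null(high)) as.numeric(high),
         osc_fraction = as.numeric(osc_fraction), osc_low = as.numeric(osc_low),
         osc_high = if (!is.null(osc_high)) as.numeric(osc_high),
         saturation = if (!is.null(saturation)) as.numeric(saturation),
         source = as.character(source)),
    class = "indicator_spec"
  )
  validate_indicator_spec(spec)
}

validate_indicator_spec <- function(spec) {
  if (!nzchar(spec$name)) stopf("indicator spec needs a non-empty name")
  if (spec$mode == "range") {
    if (is.null(spec$low) || is.null(spec$high)) {
      stopf("indicator '%s': range mode needs both low and high", spec$name)
    }
    if (spec$low >= spec$high) {
      stopf("indicator '%s': range low (%g) must be below high (%g)",
            spec$name, spec$low, spec$high)
    }
  } else if (spec$mode == "upper_threshold") {
    if (is.null(spec$high)) stopf("indicator '%s': upper_threshold needs high", spec$name)
  } else {
    if (is.null(spec$low)) stopf("indicator '%s': lower_threshold needs low", spec$name)
  }
  num <- c(spec$osc_fraction, spec$osc_low, spec$osc_high, spec$saturation)
  if (any(!is.finite(num)) || any(num < 0)) {
    stopf("indicator '%s': osc_fraction, osc_low, osc_high and saturation must be finite and non-negative",
          spec$name)
  }
  if (!is.null(spec$osc_high) && spec$osc_high <= spec$osc_low) {
    stopf("indicator '%s': osc_high (%g) must exceed osc_low (%g)",
          spec$name, spec$osc_high, spec$osc_low)
  }
  spec
}

#' @export
print.indicator_spec <- function(x, ...) {
  lim <- switch(x$mode,
    range = sprintf("%g-%g", x$low, x$high),
    upper_threshold = sprintf("<= %g", x$high),
    lower_threshold = sprintf(">= %g", x$low))
  cat(sprintf("<indicator_spec> %s [%s], %s %s\n", x$name, x$unit, x$mode, lim))
  invisible(x)
}

#' Load a standards registry from YAML or JSON
#'
#' The document holds a top-level `indicators` list, one mapping per indicator
#' with the fields of [indicator_spec()]. Files ending in `.json` are parsed
#' with jsonlite, anything else with yaml (which also accepts JSON syntax).
#'
#' @param path Path to the standards document.
#' @return A named list of `indicator_spec` objects, class `standards_registry`.
#' @seealso [default_standards()], [write_standards()]
#' @export
load_standards <- function(path) {
  if (!file.exists(path)) stopf("standards document not found: %s", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- doc$indicators %||% doc
  if (length(entries) == 0) stopf("standards document has no indicators")
  specs <- lapply(entries, function(e) {
    do.call(indicator_spec, e[!vapply(e, is.null, logical(1))])
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) {
    stopf("duplicate indicator in standards document: %s",
          paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "))
  }
  structure(specs, class = "standards_registry")
}

#' Write a standards registry back to YAML
#'
#' Inverse of [load_standards()]: re-loading the written file yields an
#' identical registry.
#'
#' @param standards A `standards_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standards <- function(standards, path) {
  entries <- lapply(unname(standards), function(s) {
    s <- unclass(s)
    s[!vapply(s, is.null, logical(1))]
  })
  yaml::write_yaml(list(indicators = entries), path, precision = 15)
  invisible(path)
}

#' Default standards registry
#'
#' The packaged registry of internationally recommended limits for the ten
#' monitored indicators: T 16-24 degC, RH 45-60 %, artificial light 50-200
#' lux (range mode, exhibit conservation); CO2 <= 1000 ppm, HCHO <= 0.04
#' mg/m3, TVOC <= 1 mg/m3, PM2.5 and PM10 <= 35 ug/m3, positive ions <= 1000
#' ions/cm3, negative ions >= 1000 ions/cm3 (threshold mode, human health).
#' Oscillation allowances and saturation levels are package defaults,
#' overridable by editing a copy of the document (see
#' `system.file("extdata", "standards_default.yaml", package = "hmrisk")`).
#'
#' @return A `standards_registry`.
#' @export
default_standards <- function() {
  load_standards(system.file("extdata", "standards_default.yaml",
                             package = "hmrisk", mustWork = TRUE))
}

#' @export
print.standards_registry <- function(x, ...) {
  cat(sprintf("<standards_registry> %d indicators\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' Range bounds adjusted by the allowed-oscillation fraction
#'
#' For a range-mode indicator the standard's limits may be widened by the
#' fraction of oscillation the standard tolerates: the upper limit is
#' multiplied by `(1 + osc_fraction)` and the lower limit by
#' `(1 - osc_fraction)`. With `osc_fraction = 0` (the default registry) the
#' published limits are returned unchanged.
#'
#' @param spec An `indicator_spec` with `mode = "range"`.
#' @return Named numeric vector `c(low = , high = )`.
#' @examples
#' s <- indicator_spec("RH", "%", "range", low = 45, high = 60,
#'                     osc_fraction = 0.03, osc_low = 3, osc_high = 10)
#' effective_bounds(s)  # 43.65, 61.8
#' @export
effective_bounds <- function(spec) {
  stopifnot(inherits(spec, "indicator_spec"))
  if (spec$mode != "range") {
    stopf("effective_bounds() applies to range-mode indicators; '%s' is %s",
          spec$name, spec$mode)
  }
  c(low = spec$low * (1 - spec$osc_fraction),
    high = spec$high * (1 + spec$osc_fraction))
}

# Adjusted oscillation bounds for range-mode oscillation scoring: the same
# multiplicative widening applied to the daily-oscillation allowance.
effective_osc_bounds <- function(spec) {
  c(low = spec$osc_low * (1 - spec$osc_fraction),
    high = spec$osc_high * (1 + spec$osc_fraction))
}

# Saturation level for threshold-mode scoring, defaulting to 2x the threshold
# (upper) or half of it (lower) when the spec does not set one.
threshold_saturation <- function(spec) {
  if (spec$mode == "upper_threshold") {
    sat <- spec$saturation %||% (2 * spec$high)
    if (sat <= spec$high) {
      stopf("indicator '%s': saturation (%g) must exceed the threshold (%g)",
            spec$name, sat, spec$high)
    }
  } else if (spec$mode == "lower_threshold") {
    sat <- spec$saturation %||% (spec$low / 2)
    if (sat >= spec$low) {
      stopf("indicator '%s': saturation (%g) must lie below the threshold (%g)",
            spec$name, sat, spec$low)
    }
  } else {
    stopf("indicator '%s' is range-mode; no threshold saturation", spec$name)
  }
  sat
}
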