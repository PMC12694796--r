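#' Mean-level risk score for a range-mode indicator
#'
#' The default (`mode = "verbatim"`) is the linear map of the period mean
#' onto the adjusted acceptability range: with bounds `(lo, hi)` from
#' [effective_bounds()],
#' `score = 1 - 2 * (hi - mean) / (hi - lo)`,
#' clamped to \[-1, 1\]. The score is 0 at the range midpoint, +1 at the
#' upper bound (excess) and -1 at the lower bound (deficit).
#'
#' `mode = "exceedance_only"` instead scores 0 whenever the mean sits inside
#' the adjusted range and, outside it, grows with both the magnitude of the
#' mean's excursion (relative to the range width) and the fraction of
#' observations beyond the bound, weighted by `alpha`; deficits are negative.
#'
#' @param stats A `series_stats` object.
#' @param spec An `indicator_spec` with `mode = "range"`.
#' @param mode `"verbatim"` (linear map, default) or `"exceedance_only"`.
#' @param alpha Weight of the magnitude term in `exceedance_only` mode.
#' @return A score in \[-1, 1\].
#' @export
hmr_env_range <- function(stats, spec, mode = c("verbatim", "exceedance_only"),
                          alpha = 0.5) {
  mode <- match.arg(mode)
  b <- effective_bounds(spec)
  lo <- b[["low"]]; hi <- b[["high"]]
  if (hi == lo) stopf("indicator '%s': degenerate range (low == high)", spec$name)
  if (mode == "verbatim") {
    raw <- 1 - ((hi - stats$mean) / (hi - lo)) * 2
    return(clamp(raw, -1, 1))
  }
  width <- hi - lo
  s_high <- alpha * clamp((stats$mean - hi) / width, 0, 1) +
    (1 - alpha) * stats$exceed_fraction_high
  s_low <- alpha * clamp((lo - stats$mean) / width, 0, 1) +
    (1 - alpha) * stats$exceed_fraction_low
  if (stats$mean >= lo && stats$mean <= hi && s_high == 0 && s_low == 0) return(0)
  clamp(s_high - s_low, -1, 1)
}

#' Oscillation risk score for a range-mode indicator
#'
#' Linear map of the mean day-to-day oscillation onto the allowed daily
#' oscillation band: with adjusted bounds `(olo, ohi)` (the spec's
#' `osc_low`/`osc_high` widened by `osc_fraction`),
#' `score = 1 - 2 * (ohi - osc_mean) / (ohi - olo)`,
#' clamped to \[-1, 1\]: 0 at the band midpoint, +1 when the mean oscillation
#' reaches the maximum allowed, -1 at the minimum.
#'
#' @inheritParams hmr_env_range
#' @return A score in \[-1, 1\].
#' @export
hmr_osc_range <- function(stats, spec) {
  if (spec$mode != "range") stopf("hmr_osc_range() needs a range-mode spec")
  b <- effective_osc_bounds(spec)
  olo <- b[["low"]]; ohi <- b[["high"]]
  if (ohi == olo) stopf("indicator '%s': degenerate oscillation band", spec$name)
  clamp(1 - ((ohi - stats$osc_mean) / (ohi - olo)) * 2, -1, 1)
}

#' Mean-level risk score for a threshold-mode indicator
#'
#' The default (`mode = "semantic"`) implements one-sided exceedance risk on
#' \[0, 1\]: 0 when no observation passes the threshold, growing with both
#' the frequency and the magnitude of exceedances,
#' `score = alpha * E_mag + (1 - alpha) * E_freq`,
#' where `E_freq` is the fraction of observations beyond the threshold and
#' `E_mag = clamp((P_mean - P_opt) / (P_sat - P_opt), 0, 1)` measures how far
#' the period mean sits between the threshold `P_opt` and the saturation
#' level `P_sat` (see [indicator_spec()]). For a lower threshold the axis is
#' mirrored: risk comes from the deficit below the limit.
#'
#' `mode = "verbatim"` evaluates the alternative linear form
#' `1 - 2 * (P_mean - P_opt) / (P_max - P_opt)` (0 below the threshold,
#' clamped to \[0, 1\]), retained for auditability; note its gradient runs
#' opposite to the semantic scale, scoring high for means just past the
#' threshold.
#'
#' @param stats A `series_stats` object.
#' @param spec An `indicator_spec` with threshold mode.
#' @param mode `"semantic"` (default) or `"verbatim"`.
#' @param alpha Weight of the magnitude term, default 0.5.
#' @return A score in \[0, 1\].
#' @export
hmr_env_threshold <- function(stats, spec, mode = c("semantic", "verbatim"),
                              alpha = 0.5) {
  mode <- match.arg(mode)
  if (!spec$mode %in% c("upper_threshold", "lower_threshold")) {
    stopf("hmr_env_threshold() needs a threshold-mode spec")
  }
  sat <- threshold_saturation(spec)
  if (spec$mode == "upper_threshold") {
    p_opt <- spec$high
    e_freq <- stats$exceed_fraction_high
    e_mag <- clamp((stats$mean - p_opt) / (sat - p_opt), 0, 1)
    over <- stats$mean > p_opt
  } else {
    p_opt <- spec$low
    e_freq <- stats$exceed_fraction_low
    e_mag <- clamp((p_opt - stats$mean) / (p_opt - sat), 0, 1)
    over <- stats$mean < p_opt
  }
  if (mode == "semantic") {
    if (e_freq == 0) return(0)
    return(clamp(alpha * e_mag + (1 - alpha) * e_freq, 0, 1))
  }
  # verbatim linear form; sub-threshold means score 0 outright
  if (!over) return(0)
  clamp(1 - 2 * abs(stats$mean - p_opt) / abs(sat - p_opt), 0, 1)
}

#' Oscillation risk score for a threshold-mode indicator
#'
#' The default (`mode = "semantic"`) locates the mean day-to-day variation
#' between the safe floor `dP_opt` (the spec's `osc_low`) and the worst
#' observed variation `dP_max` (`osc_max` from [series_stats()]):
#' `score = clamp((dP_mean - dP_opt) / (dP_max - dP_opt), 0, 1)`,
#' 0 when average variation is at or below the safe floor and approaching 1
#' as it approaches the worst observed change. When `dP_max <= dP_opt`
#' (no variation beyond the floor) the score is 0.
#'
#' `mode = "verbatim"` evaluates the alternative linear form
#' `1 - 2 * (dP_max - dP_mean) / (dP_max - dP_opt)`, clamped to \[0, 1\].
#'
#' @inheritParams hmr_env_threshold
#' @return A score in \[0, 1\].
#' @export
hmr_osc_threshold <- function(stats, spec, mode = c("semantic", "verbatim")) {
  mode <- match.arg(mode)
  if (!spec$mode %in% c("upper_threshold", "lower_threshold")) {
    stopf("hmr_osc_threshold() needs a threshold-mode spec")
  }
  dp_opt <- spec$osc_low
  dp_max <- stats$osc_max
  dp_mean <- stats$osc_mean
  if (dp_max <= dp_opt) return(0)
  if (mode == "semantic") {
    return(clamp((dp_mean - dp_opt) / (dp_max - dp_opt), 0, 1))
  }
  clamp(1 - 2 * (dp_max - dp_mean) / (dp_max - dp_opt), 0, 1)
}

#' Combine the mean-level and oscillation components
#'
#' The combined index is the exact arithmetic mean of the two components.
#'
#' @param env,osc Finite component scores.
#' @return `(env + osc) / 2`.
#' @examples
#' hmr_combine(0.56, 0.88)  # 0.72
#' @export
hmr_combine <- function(env, osc) {
  if (any(!is.finite(env)) || any(!is.finite(osc))) stopf("components must be finite")
  (env + osc) / 2
}

#' Classify a score into a risk band
#'
#' Scores are banded by absolute value: below 0.2 `"low"`, 0.2 up to 0.6
#' `"moderate"`, 0.6 and above `"high"`. The conservation index lives on
#' \[-1, 1\] and a negative score carries the qualifier `"deficit"`
#' (below-minimum conditions), a positive one `"excess"`; the health index
#' lives on \[0, 1\] and is one-sided. Band cut-points are configurable.
#'
#' @param score Numeric score(s).
#' @param family `"hmr_e"` (conservation, domain \[-1, 1\]) or `"hmr_h"`
#'   (health, domain \[0, 1\]).
#' @param cuts Two increasing cut-points on |score|, default `c(0.2, 0.6)`.
#' @param direction If `TRUE`, append `/excess` or `/deficit` to non-zero
#'   conservation-index bands.
#' @return Character vector of band labels.
#' @examples
#' classify_risk(0.4, "hmr_e")             # "moderate"
#' classify_risk(-1, "hmr_e", direction = TRUE)  # "high/deficit"
#' @export
classify_risk <- function(score, family = c("hmr_e", "hmr_h"),
                          cuts = c(0.2, 0.6), direction = FALSE) {
  family <- match.arg(family)
  lo_dom <- if (family == "hmr_e") -1 else 0
  if (any(score < lo_dom - 1e-12 | score > 1 + 1e-12)) {
    stopf("score outside the [%g, 1] domain of %s", lo_dom, family)
  }
  band <- ifelse(abs(score) < cuts[1], "low",
                 ifelse(abs(score) < cuts[2], "moderate", "high"))
  if (direction && family == "hmr_e") {
    qual <- ifelse(score > 0, "/excess", ifelse(score < 0, "/deficit", ""))
    band <- paste0(band, qual)
  }
  band
}
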