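#' Average component scores across the indicators of one room
#'
#' Unweighted arithmetic mean of each component (mean-level, oscillation,
#' combined) across indicators — the "room average" column of an assessment
#' table.
#'
#' @param scores A tibble (or data frame) with numeric columns `hmr_env`,
#'   `hmr_osc`, `hmr`, one row per indicator.
#' @return A one-row tibble with the three averaged components.
#' @examples
#' room_average(tibble::tibble(hmr_env = c(0.14, 0.56, -0.35),
#'                             hmr_osc = c(0.47, 0.88, 0.66),
#'                             hmr = c(0.3, 0.72, 0.15)))
#' @export
room_average <- function(scores) {
  if (nrow(scores) == 0) stopf("room_average(): no scores")
  tibble::tibble(hmr_env = mean(scores$hmr_env),
                 hmr_osc = mean(scores$hmr_osc),
                 hmr = mean(scores$hmr))
}

#' Average room-level triples into the overall score
#'
#' @param room_triples A tibble with columns `hmr_env`, `hmr_osc`, `hmr`,
#'   one row per room.
#' @return A one-row tibble of overall averages.
#' @examples
#' overall_average(tibble::tibble(hmr_env = c(0.12, 0.15),
#'                                hmr_osc = c(0.67, 0.67),
#'                                hmr = c(0.39, 0.41)))
#' @export
overall_average <- function(room_triples) {
  if (nrow(room_triples) == 0) stopf("overall_average(): no rooms")
  tibble::tibble(hmr_env = mean(room_triples$hmr_env),
                 hmr_osc = mean(room_triples$hmr_osc),
                 hmr = mean(room_triples$hmr))
}

#' Assess a monitoring campaign
#'
#' Runs the full scoring pipeline over one or more rooms: per indicator it
#' computes [series_stats()], scores the mean-level and oscillation
#' components under the indicator's mode (range indicators feed the
#' conservation index `hmr_e`, threshold indicators the health index
#' `hmr_h`), combines them with [hmr_combine()], then averages per room and
#' overall and attaches risk bands.
#'
#' @param x Either a list of [room_dataset()] objects, a single
#'   `room_dataset`, or a long `hmr_ts` tibble from [read_timeseries()]
#'   (sensors are then averaged per room with [aggregate_room()]).
#' @param standards A `standards_registry`; defaults to the packaged registry.
#'   Indicators present in the data but absent from the registry are skipped
#'   with a warning and listed in the result's `missing` field, as are
#'   registry indicators absent from a room's data.
#' @param range_mode Scoring mode for range indicators, `"verbatim"` or
#'   `"exceedance_only"` (see [hmr_env_range()]).
#' @param threshold_mode Scoring mode for threshold indicators, `"semantic"`
#'   or `"verbatim"` (see [hmr_env_threshold()]).
#' @param alpha Magnitude weight of the semantic threshold score.
#' @param cuts Risk-band cut-points passed to [classify_risk()].
#' @return An object of class `hmr_assessment`: a list with
#'   \describe{
#'     \item{scores}{tibble of per-indicator component scores and bands;}
#'     \item{room_averages}{tibble of per-room averaged triples per family;}
#'     \item{overall}{tibble of overall triples per family;}
#'     \item{missing}{tibble of (room, indicator, reason) skipped;}
#'     \item{modes}{the scoring modes used.}
#'   }
#' @export
assess_campaign <- function(x, standards = default_standards(),
                            range_mode = c("verbatim", "exceedance_only"),
                            threshold_mode = c("semantic", "verbatim"),
                            alpha = 0.5, cuts = c(0.2, 0.6)) {
  range_mode <- match.arg(range_mode)
  threshold_mode <- match.arg(threshold_mode)
  datasets <- as_room_datasets(x)

  rows <- list(); miss <- list()
  for (ds in datasets) {
    for (ind in names(ds$series)) {
      spec <- standards[[ind]]
      if (is.null(spec)) {
        miss[[length(miss) + 1L]] <- tibble::tibble(
          room = ds$room, indicator = ind, reason = "no standard in registry")
        next
      }
      st <- series_stats(ds$series[[ind]], spec)
      if (spec$mode == "range") {
        env <- hmr_env_range(st, spec, mode = range_mode, alpha = alpha)
        osc <- hmr_osc_range(st, spec)
        fam <- "hmr_e"
      } else {
        env <- hmr_env_threshold(st, spec, mode = threshold_mode, alpha = alpha)
        osc <- hmr_osc_threshold(st, spec, mode = threshold_mode)
        fam <- "hmr_h"
      }
      hmr <- hmr_combine(env, osc)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = fam, room = ds$room, indicator = ind, n = st$n,
        mean = st$mean, hmr_env = env, hmr_osc = osc, hmr = hmr,
        band = classify_risk(hmr, fam, cuts = cuts, direction = (fam == "hmr_e")))
    }
    absent <- setdiff(names(standards), names(ds$series))
    for (ind in absent) {
      miss[[length(miss) + 1L]] <- tibble::tibble(
        room = ds$room, indicator = ind, reason = "indicator not monitored")
    }
  }
  scores <- dplyr::bind_rows(rows)
  if (nrow(scores) == 0) stopf("no indicator could be scored")
  missing <- if (length(miss)) dplyr::bind_rows(miss) else
    tibble::tibble(room = character(), indicator = character(), reason = character())
  if (any(missing$reason == "no standard in registry")) {
    warning(sprintf("skipped indicators without a standard: %s",
                    paste(unique(missing$indicator[missing$reason == "no standard in registry"]),
                          collapse = ", ")), call. = FALSE)
  }

  room_averages <- scores |>
    dplyr::group_by(.data$family, .data$room) |>
    dplyr::group_modify(~ room_average(.x)) |>
    dplyr::ungroup()
  overall <- room_averages |>
    dplyr::group_by(.data$family) |>
    dplyr::group_modify(~ overall_average(.x)) |>
    dplyr::ungroup()
  room_averages$band <- unlist(Map(classify_risk, room_averages$hmr, room_averages$family,
                                   MoreArgs = list(cuts = cuts)))
  overall$band <- unlist(Map(classify_risk, overall$hmr, overall$family,
                             MoreArgs = list(cuts = cuts)))

  structure(list(scores = scores, room_averages = room_averages,
                 overall = overall, missing = missing,
                 modes = list(range_mode = range_mode,
                              threshold_mode = threshold_mode, alpha = alpha,
                              cuts = cuts)),
            class = "hmr_assessment")
}

as_room_datasets <- function(x) {
  if (inherits(x, "room_dataset")) return(list(x))
  if (is.data.frame(x)) {
    agg <- aggregate_all(x)
    out <- lapply(split(agg, agg$room), function(part) {
      room_dataset(part$room[1], split(part, part$indicator))
    })
    return(out)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "room_dataset"))) return(x)
  stopf("cannot interpret input as room datasets")
}

#' @export
print.hmr_assessment <- function(x, digits = 2, ...) {
  cat("<hmr_assessment>\n")
  for (fam in unique(x$overall$family)) {
    ov <- x$overall[x$overall$family == fam, ]
    lab <- if (fam == "hmr_e") "HMR_E (conservation)" else "HMR_H (health)"
    cat(sprintf("  %s overall: %s (%s)\n", lab,
                format(round_half_up(ov$hmr, digits)), ov$band))
  }
  cat(sprintf("  %d indicator scores across %d room(s); see $scores\n",
              nrow(x$scores), length(unique(x$scores$room))))
  if (nrow(x$missing)) cat(sprintf("  %d room-indicator pairs skipped; see $missing\n",
                                   nrow(x$missing)))
  invisible(x)
}

#' Render an assessment as a wide report table
#'
#' One row per component (`HMR_env`, `HMR_osc`, and the combined index),
#' one column per room-indicator pair followed by each room's average and the
#' overall average — the conventional layout of a microclimate risk report.
#'
#' @param assessment An `hmr_assessment`.
#' @param family `"hmr_e"` or `"hmr_h"`.
#' @param digits Report rounding (half away from zero); `NULL` for full
#'   precision.
#' @return A tibble with a `component` column followed by score columns.
#' @export
assessment_table <- function(assessment, family = c("hmr_e", "hmr_h"),
                             digits = 2) {
  family <- match.arg(family)
  sc <- assessment$scores[assessment$scores$family == family, ]
  if (nrow(sc) == 0) stopf("assessment has no %s scores", family)
  ra <- assessment$room_averages[assessment$room_averages$family == family, ]
  ov <- assessment$overall[assessment$overall$family == family, ]
  comb_label <- if (family == "hmr_e") "HMR_E" else "HMR_H"
  rnd <- function(v) if (is.null(digits)) v else round_half_up(v, digits)

  cols <- list(component = c("HMR_env", "HMR_osc", comb_label))
  for (room in unique(sc$room)) {
    part <- sc[sc$room == room, ]
    for (i in seq_len(nrow(part))) {
      cols[[paste(room, part$indicator[i], sep = ":")]] <-
        rnd(c(part$hmr_env[i], part$hmr_osc[i], part$hmr[i]))
    }
    r <- ra[ra$room == room, ]
    cols[[paste(room, "room_average", sep = ":")]] <-
      rnd(c(r$hmr_env, r$hmr_osc, r$hmr))
  }
  cols[["overall_average"]] <- rnd(c(ov$hmr_env, ov$hmr_osc, ov$hmr))
  tibble::as_tibble(cols)
}
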