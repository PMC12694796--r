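#' Run the assessment pipeline and write its report artifacts
#'
#' Reads one or more time-series CSVs (or takes room datasets directly),
#' aggregates sensors per room, assesses both indices and writes to
#' `out_dir`: `hmr_e.csv` and `hmr_h.csv` (the wide report tables of
#' [assessment_table()]), `assessment.json` (all scores, averages and bands
#' at full precision) and `manifest.json` (package version, scoring modes,
#' standards-file and input checksums, and any room-indicator pairs skipped).
#' Outputs contain no timestamps, so identical inputs and configuration
#' produce byte-identical artifacts.
#'
#' A registry indicator missing from a room's data is a warning, not an
#' error: the assessment proceeds with the remaining indicators and the gap
#' is listed in the manifest.
#'
#' @param input CSV path(s) in the layout of [read_timeseries()], or a list
#'   of [room_dataset()] objects.
#' @param out_dir Output directory (created if needed).
#' @param standards_path Optional standards document; defaults to the
#'   packaged registry.
#' @param range_mode,threshold_mode,alpha,cuts Passed to [assess_campaign()].
#' @param digits Report rounding for the CSV tables.
#' @return The `hmr_assessment`, invisibly.
#' @export
run_assess <- function(input, out_dir, standards_path = NULL,
                       range_mode = "verbatim", threshold_mode = "semantic",
                       alpha = 0.5, cuts = c(0.2, 0.6), digits = 2) {
  standards <- if (is.null(standards_path)) default_standards()
               else load_standards(standards_path)
  input_files <- character(0)
  if (is.character(input)) {
    input_files <- input
    ts <- dplyr::bind_rows(lapply(input, read_timeseries, standards = standards))
    x <- ts
  } else {
    x <- input
  }
  assessment <- assess_campaign(x, standards = standards, range_mode = range_mode,
                                threshold_mode = threshold_mode, alpha = alpha,
                                cuts = cuts)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (fam in unique(assessment$scores$family)) {
    tbl <- assessment_table(assessment, fam, digits = digits)
    readr::write_csv(tbl, file.path(out_dir, paste0(fam, ".csv")), progress = FALSE)
  }
  jsonlite::write_json(
    list(scores = assessment$scores, room_averages = assessment$room_averages,
         overall = assessment$overall, missing = assessment$missing),
    file.path(out_dir, "assessment.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "hmrisk",
    version = as.character(utils::packageVersion("hmrisk")),
    modes = assessment$modes,
    standards = if (is.null(standards_path)) "packaged default"
                else unname(tools::md5sum(standards_path)),
    inputs = if (length(input_files)) as.list(tools::md5sum(input_files))
             else "in-memory room datasets",
    skipped = assessment$missing)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(assessment)
}

#' Run the colony-count efficacy stage and write its artifacts
#'
#' Reads a colony-count CSV, computes CFU/g and the treated-vs-untreated
#' persistence comparison, and writes `persistence.csv` (per-sample table)
#' and `cfu_summary.json` to `out_dir`.
#'
#' @param input Colony-count CSV path (see [read_colony_records()]).
#' @param out_dir Output directory.
#' @param reporting_limit,ceiling Passed to [persistence_summary()].
#' @return The `hmr_persistence` object, invisibly.
#' @export
run_cfu <- function(input, out_dir, reporting_limit = 10, ceiling = 300) {
  records <- read_colony_records(input)
  res <- persistence_summary(records, reporting_limit = reporting_limit,
                             ceiling = ceiling)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$per_sample, file.path(out_dir, "persistence.csv"),
                   progress = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "cfu_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Simulate the demonstration campaign and write it as CSV
#'
#' @param out_csv Output CSV path (layout of [read_timeseries()]).
#' @param n_days,seed Passed to [demo_campaign()].
#' @return The list of room datasets, invisibly.
#' @export
run_simulate <- function(out_csv, n_days = 240, seed = 20240101) {
  datasets <- demo_campaign(n_days = n_days, seed = seed)
  write_timeseries(campaign_to_ts(datasets), out_csv)
  invisible(datasets)
}
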