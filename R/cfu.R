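#' Colony counts to CFU per gram
#'
#' Converts plate colony counts to colony-forming units per gram of sample:
#' `CFU/g = NCC * DF / VP`, where `NCC` is the number of colonies counted,
#' `DF` the dilution factor (default 50, a 1:50 dilution) and `VP` the
#' volume plated in mL (default 1). Censored plates pass through as censored
#' results: `below_detection` (no countable colony) becomes a left-censored
#' value at the assay's reporting limit, `uncountable` (confluent growth
#' above the countability ceiling) a right-censored value at
#' `ceiling * DF / VP`.
#'
#' @param records A tibble of colony records with columns `sample_id`, `arm`
#'   (`"untreated"`/`"treated"`), `test` (`"t1"`/`"t2"`), `ncc` (non-negative
#'   integer count, or the marks `"below_detection"` / `"uncountable"`), and
#'   optionally `dilution_factor`, `volume_plated_ml` (defaults filled in).
#' @param reporting_limit CFU/g value under which a below-detection plate is
#'   reported (default 10, the conventional "< 10" entry).
#' @param ceiling Countability ceiling in colonies per plate (default 300).
#' @return A tibble with the input identifiers plus `cfu_per_g` (numeric, NA
#'   when censored), `censor` (`"none"`, `"lt"`, `"gt"`), `limit` (the
#'   reporting bound for censored rows) and `detection_limit` (`DF / VP`,
#'   the CFU/g equivalent of a single colony).
#' @examples
#' cfu_per_g(tibble::tibble(sample_id = "5", arm = "untreated", test = "t2",
#'                          ncc = "107"))  # 5350 CFU/g
#' @export
cfu_per_g <- function(records, reporting_limit = 10, ceiling = 300) {
  records <- normalize_colony_records(records)
  ncc_num <- suppressWarnings(as.numeric(records$ncc))
  is_mark <- records$ncc %in% c("below_detection", "uncountable")
  bad <- !is_mark & (is.na(ncc_num) | ncc_num < 0 | ncc_num != floor(ncc_num))
  if (any(bad)) {
    stopf("invalid colony count(s): %s",
          paste(utils::head(unique(records$ncc[bad]), 5), collapse = ", "))
  }
  df <- records$dilution_factor
  vp <- records$volume_plated_ml
  scale <- df / vp
  # a zero count means no countable colony at this dilution: below detection
  zero <- !is_mark & ncc_num == 0
  cfu <- ifelse(is_mark | zero, NA_real_, ncc_num * scale)
  censor <- ifelse(records$ncc == "below_detection" | zero, "lt",
                   ifelse(records$ncc == "uncountable", "gt", "none"))
  limit <- ifelse(censor == "lt", reporting_limit,
                  ifelse(censor == "gt", ceiling * scale, NA_real_))
  tibble::tibble(sample_id = records$sample_id, arm = records$arm,
                 test = records$test, cfu_per_g = cfu, censor = censor,
                 limit = limit, detection_limit = scale)
}

normalize_colony_records <- function(records) {
  needed <- c("sample_id", "arm", "test", "ncc")
  if (!all(needed %in% names(records))) {
    stopf("colony records need columns %s", paste(needed, collapse = ", "))
  }
  if (!all(records$arm %in% c("untreated", "treated"))) {
    stopf("arm must be 'untreated' or 'treated'")
  }
  if (!all(records$test %in% c("t1", "t2"))) stopf("test must be 't1' or 't2'")
  records$ncc <- as.character(records$ncc)
  if (!"dilution_factor" %in% names(records)) records$dilution_factor <- 50
  if (!"volume_plated_ml" %in% names(records)) records$volume_plated_ml <- 1
  if (any(records$dilution_factor <= 0) || any(records$volume_plated_ml <= 0)) {
    stopf("dilution_factor and volume_plated_ml must be positive")
  }
  records
}

#' Read colony-count records from CSV
#'
#' Expected header: `sample_id,arm,test,ncc_or_mark,dilution_factor,`
#' `volume_plated_ml` (the last two optional). `ncc_or_mark` holds either an
#' integer colony count or the marks `below_detection` / `uncountable`.
#'
#' @param path CSV path.
#' @return A tibble of colony records suitable for [cfu_per_g()].
#' @export
read_colony_records <- function(path) {
  if (!file.exists(path)) stopf("colony-count file not found: %s", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) stopf("colony-count file is empty: %s", path)
  if (!"ncc_or_mark" %in% names(raw) && !"ncc" %in% names(raw)) {
    stopf("colony-count CSV needs an ncc_or_mark column")
  }
  col <- function(name, default) {
    if (name %in% names(raw)) raw[[name]] else default
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id, arm = raw$arm, test = raw$test,
    ncc = col("ncc_or_mark", col("ncc", NA_character_)),
    dilution_factor = as.numeric(col("dilution_factor", 50)),
    volume_plated_ml = as.numeric(col("volume_plated_ml", 1)))
  dup <- duplicated(out[c("sample_id", "arm", "test")])
  if (any(dup)) {
    stopf("conflicting duplicate colony records for sample(s): %s",
          paste(unique(out$sample_id[dup]), collapse = ", "))
  }
  normalize_colony_records(out)
}

#' Treated-versus-untreated persistence summary
#'
#' Summarises an antimicrobial-efficacy assay run as two arms (untreated,
#' treated) at two dates (t1, and t2 thirty days later): per sample and arm
#' the CFU/g at each test and the fold change t1 -> t2; per sample the arm
#' contrast at each test; and overall, the number of samples where the
#' treated arm sits below the untreated arm at t2. All comparisons are
#' censoring-aware: a fold change against a censored value is reported as a
#' bound (`">= x"` / `"<= x"`) or as indeterminate when both sides are
#' censored the same way, and an arm contrast is `"bound-certain"` when
#' censoring itself forces the ordering (right-censored untreated vs
#' left-censored treated).
#'
#' @param records A tibble of colony records (see [cfu_per_g()]).
#' @param reporting_limit,ceiling Passed to [cfu_per_g()].
#' @return An object of class `hmr_persistence`: a list with `per_sample`
#'   (one row per sample: CFU columns per arm and test, fold changes, arm
#'   contrasts, a `stable_low` flag for treated arms censored low at both
#'   tests), `cfu` (the long CFU table) and `summary` (counts and the
#'   mean-based log10 reduction estimate from [estimate_log_reduction()]).
#' @export
persistence_summary <- function(records, reporting_limit = 10, ceiling = 300) {
  cfu <- cfu_per_g(records, reporting_limit = reporting_limit, ceiling = ceiling)
  if (anyDuplicated(cfu[c("sample_id", "arm", "test")])) {
    stopf("conflicting duplicate records (same sample, arm and test)")
  }
  fmt <- function(value, censor, limit) {
    ifelse(censor == "lt", sprintf("< %g", limit),
           ifelse(censor == "gt", "uncountable", sprintf("%g", value)))
  }
  cfu$display <- fmt(cfu$cfu_per_g, cfu$censor, cfu$limit)

  get1 <- function(sample, arm, test) {
    row <- cfu[cfu$sample_id == sample & cfu$arm == arm & cfu$test == test, ]
    if (nrow(row) == 0) NULL else row
  }
  fold_change <- function(a, b) {  # b relative to a (t1 -> t2)
    if (is.null(a) || is.null(b)) return(list(value = NA_real_, label = NA_character_))
    av <- if (a$censor == "none") a$cfu_per_g else a$limit
    bv <- if (b$censor == "none") b$cfu_per_g else b$limit
    if (a$censor == "none" && b$censor == "none") {
      return(list(value = bv / av, label = sprintf("%g", bv / av)))
    }
    if (a$censor == "lt" && b$censor == "lt") {
      return(list(value = NA_real_, label = "indeterminate (both < limit)"))
    }
    if (a$censor == "gt" && b$censor == "gt") {
      return(list(value = NA_real_, label = "indeterminate (both uncountable)"))
    }
    # one-sided bounds: censored numerator -> bound on the ratio
    if (b$censor == "gt" || a$censor == "lt") {
      return(list(value = NA_real_, label = sprintf(">= %g", bv / av)))
    }
    list(value = NA_real_, label = sprintf("<= %g", bv / av))
  }
  contrast <- function(u, t) {  # treated vs untreated at one test
    if (is.null(u) || is.null(t)) return(NA_character_)
    if (u$censor == "gt" && t$censor == "lt") return("treated < untreated (bound-certain)")
    if (u$censor == "none" && t$censor == "none") {
      if (t$cfu_per_g < u$cfu_per_g) return("treated < untreated")
      if (t$cfu_per_g > u$cfu_per_g) return("treated > untreated")
      return("equal")
    }
    if (t$censor == "lt" && u$censor == "none" && u$cfu_per_g >= t$limit) {
      return("treated < untreated")
    }
    if (u$censor == "gt" && t$censor == "none") return("treated < untreated")
    if (t$censor == "gt" && u$censor %in% c("none", "lt")) return("treated > untreated")
    "indeterminate"
  }

  samples <- unique(cfu$sample_id)
  per_sample <- dplyr::bind_rows(lapply(samples, function(s) {
    u1 <- get1(s, "untreated", "t1"); u2 <- get1(s, "untreated", "t2")
    t1 <- get1(s, "treated", "t1");   t2 <- get1(s, "treated", "t2")
    fu <- fold_change(u1, u2); ft <- fold_change(t1, t2)
    tibble::tibble(
      sample_id = s,
      untreated_t1 = if (is.null(u1)) NA_character_ else u1$display,
      treated_t1 = if (is.null(t1)) NA_character_ else t1$display,
      untreated_t2 = if (is.null(u2)) NA_character_ else u2$display,
      treated_t2 = if (is.null(t2)) NA_character_ else t2$display,
      fold_change_untreated = fu$value, fold_change_untreated_label = fu$label,
      fold_change_treated = ft$value, fold_change_treated_label = ft$label,
      contrast_t1 = contrast(u1, t1), contrast_t2 = contrast(u2, t2),
      stable_low = !is.null(t1) && !is.null(t2) &&
        t1$censor == "lt" && t2$censor == "lt")
  }))

  treated_lower_t2 <- sum(grepl("^treated < untreated", per_sample$contrast_t2),
                          na.rm = TRUE)
  structure(list(
    per_sample = per_sample, cfu = cfu,
    summary = list(
      n_samples = length(samples),
      n_treated_below_untreated_t2 = treated_lower_t2,
      n_stable_low_treated = sum(per_sample$stable_low),
      log10_reduction = estimate_log_reduction(records, ceiling = ceiling))),
    class = "hmr_persistence")
}

#' @export
print.hmr_persistence <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<hmr_persistence> %d samples; treated < untreated at t2 in %d;",
                     " %d treated arms stable-low\n  estimated log10 reduction: %.3f\n"),
              s$n_samples, s$n_treated_below_untreated_t2, s$n_stable_low_treated,
              s$log10_reduction))
  print(x$per_sample[, c("sample_id", "untreated_t1", "treated_t1",
                         "untreated_t2", "treated_t2")])
  invisible(x)
}

#' Mean-based log10 reduction estimate
#'
#' Estimates the antimicrobial effect as
#' `log10(mean untreated CFU/g / mean treated CFU/g)` pooled over samples and
#' tests. Censored plates enter at their bounding count: below-detection as 0
#' and uncountable at the countability ceiling, so the estimate is
#' conservative when heavy censoring is present.
#'
#' @param records A tibble of colony records.
#' @param ceiling Countability ceiling (colonies per plate).
#' @return The estimated log10 reduction (may be `Inf` when the treated arm
#'   has no detectable growth at all).
#' @export
estimate_log_reduction <- function(records, ceiling = 300) {
  records <- normalize_colony_records(records)
  scale <- records$dilution_factor / records$volume_plated_ml
  ncc <- suppressWarnings(as.numeric(records$ncc))
  ncc[records$ncc == "below_detection"] <- 0
  ncc[records$ncc == "uncountable"] <- ceiling
  cfu <- ncc * scale
  mu_u <- mean(cfu[records$arm == "untreated"])
  mu_t <- mean(cfu[records$arm == "treated"])
  if (is.na(mu_u) || is.na(mu_t) || mu_u <= 0) return(NA_real_)
  if (mu_t == 0) return(Inf)
  log10(mu_u / mu_t)
}

#' Simulate a plate-count efficacy assay
#'
#' Draws colony counts from Poisson distributions: the untreated arm at
#' `mean_colonies` expected colonies per plate, the treated arm at
#' `mean_colonies * 10^(-log10_reduction)`. Counts above the countability
#' ceiling are recorded as `uncountable`, zero counts as `below_detection`.
#' Fully reproducible from `seed`.
#'
#' @param mean_colonies Expected colonies per untreated plate (> 0).
#' @param log10_reduction Treatment effect in log10 units (>= 0).
#' @param n_samples Number of samples (> 0); each yields one record per arm
#'   per test.
#' @param seed Integer seed.
#' @param tests Test dates to simulate, default both `"t1"` and `"t2"`.
#' @param dilution_factor,volume_plated_ml Assay constants.
#' @param ceiling Countability ceiling (colonies per plate).
#' @return A tibble of colony records.
#' @export
simulate_assay <- function(mean_colonies, log10_reduction, n_samples, seed,
                           tests = c("t1", "t2"), dilution_factor = 50,
                           volume_plated_ml = 1, ceiling = 300) {
  if (mean_colonies <= 0) stopf("mean_colonies must be positive")
  if (log10_reduction < 0) stopf("log10_reduction must be non-negative")
  if (n_samples <= 0) stopf("n_samples must be positive")
  mu <- c(untreated = mean_colonies,
          treated = mean_colonies * 10^(-log10_reduction))
  with_seed(seed, {
    grid <- expand.grid(sample_id = as.character(seq_len(n_samples)),
                        arm = names(mu), test = tests,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    counts <- stats::rpois(nrow(grid), mu[grid$arm])
    ncc <- as.character(counts)
    ncc[counts == 0] <- "below_detection"
    ncc[counts > ceiling] <- "uncountable"
    tibble::tibble(sample_id = grid$sample_id, arm = grid$arm, test = grid$test,
                   ncc = ncc, dilution_factor = dilution_factor,
                   volume_plated_ml = volume_plated_ml)
  })
}
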