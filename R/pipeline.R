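#' Flag duplicate interventions
#'
#' The model must not value the same intervention twice for the same
#' patient. Records sharing the duplicate key are kept once (first
#' occurrence in input order); later occurrences are flagged so downstream
#' totals can exclude them. The default key is
#' `(hospital, patient_id, pcne_cause, period)` when a `patient_id` column
#' is present, else `(hospital, pcne_cause, period)`; override with
#' `key_cols`.
#'
#' @param records A validated record data frame.
#' @param key_cols Character vector of columns forming the duplicate key.
#' @return The records tibble with a logical `duplicate` column.
#' @export
flag_duplicates <- function(records, key_cols = NULL) {
  records <- validate_records(records)
  if (is.null(key_cols)) {
    key_cols <- if ("patient_id" %in% names(records)) {
      c("hospital", "patient_id", "pcne_cause", "period")
    } else {
      c("hospital", "pcne_cause", "period")
    }
  }
  missing_cols <- setdiff(key_cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("duplicate key columns absent: ", paste(missing_cols, collapse = ", ")),
          class = "dtp_validation_error")
  }
  mutate(records, duplicate = duplicated(records[key_cols]))
}

read_table_checked <- function(path, validator) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "dtp_io_error")
  validator(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read / write investment and coverage ledgers (CSV)
#'
#' @param path File path.
#' @param ledger A ledger data frame.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @export
read_investment <- function(path) read_table_checked(path, validate_investment)

#' @rdname read_investment
#' @export
read_coverage <- function(path) read_table_checked(path, validate_coverage)

#' @rdname read_investment
#' @export
write_investment <- function(ledger, path) {
  readr::write_csv(validate_investment(ledger), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_investment
#' @export
write_coverage <- function(ledger, path) {
  readr::write_csv(validate_coverage(ledger), path, progress = FALSE)
  invisible(path)
}

#' Pipeline stages: simulate, compute, report
#'
#' Thin file-level wrappers binding the generator, the per-record engine
#' and the aggregate reports into a reproducible pipeline; these back the
#' command-line interface but are equally usable from R.
#'
#' `cmd_simulate()` writes `records.csv`, `investment.csv` and
#' `coverage.csv` for a seeded synthetic cohort. `cmd_compute()` reads
#' records, flags duplicate interventions (whose avoidance is excluded
#' from totals, with the exclusion count reported), evaluates the model
#' under the requested costing method(s) and writes one
#' `results_<method>.csv` per method. `cmd_report()` writes one grouped
#' breakdown CSV per requested key plus a machine-readable `summary.json`
#' holding every aggregate metric (totals, averages, rates, coverage, ROI
#' series, scenario impact).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_records,seed,config Cohort settings for `cmd_simulate()`;
#'   `config` overrides the other two when given.
#' @param records_path,investment_path,coverage_path Input file paths.
#' @param params A `dtp_params` object.
#' @param method `"cleo_panel"`, `"lit"` or `"both"`.
#' @param group_by Character vector of grouping keys for `cmd_report()`.
#' @param start_year Calendar year of month index 1.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list describing the written files (and for
#'   `cmd_compute()`, the number of duplicate rows excluded).
#' @export
cmd_simulate <- function(out_dir, n_records = 1000, seed = 1, config = NULL,
                         quiet = FALSE) {
  config <- config %||% cohort_config(n_records = n_records, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  paths <- list(
    records = file.path(out_dir, "records.csv"),
    investment = file.path(out_dir, "investment.csv"),
    coverage = file.path(out_dir, "coverage.csv")
  )
  write_records(cohort$records, paths$records)
  write_investment(cohort$investment, paths$investment)
  write_coverage(cohort$coverage, paths$coverage)
  if (!quiet) message(sprintf("simulated %d records over %d months -> %s",
                              nrow(cohort$records), config$months, out_dir))
  invisible(c(paths, list(cohort = cohort)))
}

#' @rdname cmd_simulate
#' @export
cmd_compute <- function(records_path, out_dir, params = model_parameters(),
                        method = c("cleo_panel", "lit", "both"), quiet = FALSE) {
  method <- match.arg(method)
  methods <- if (method == "both") .method_levels else method
  records <- read_records(records_path)
  records <- flag_duplicates(records)
  n_dup <- sum(records$duplicate)
  if (!quiet && n_dup > 0) {
    message(sprintf("excluding %d duplicate intervention(s) from totals", n_dup))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (m in methods) {
    res <- cost_avoidance(records, params, m)
    p <- file.path(out_dir, paste0("results_", m, ".csv"))
    readr::write_csv(tidy_results(res), p, progress = FALSE)
    paths[[m]] <- p
  }
  invisible(list(paths = paths, n_duplicates_excluded = n_dup))
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(records_path, investment_path, coverage_path, out_dir,
                       params = model_parameters(),
                       group_by = c("criticality", "pcne_cause",
                                    "intervention_group", "atc_category"),
                       start_year = 2018, quiet = FALSE) {
  records <- read_records(records_path)
  investment <- read_investment(investment_path)
  coverage_ledger <- read_coverage(coverage_path)
  records <- filter(flag_duplicates(records), !.data$duplicate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- cost_avoidance(records, params, "cleo_panel")
  paths <- list()
  for (key in group_by) {
    rep <- grouped_report(res, records, key, params = params)
    p <- file.path(out_dir, paste0("report_", key, ".csv"))
    readr::write_csv(render_report(rep), p, progress = FALSE)
    paths[[key]] <- p
  }
  summary <- summarise_cohort(records, investment, coverage_ledger, params,
                              start_year)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!quiet) message("report written to ", out_dir)
  invisible(list(paths = paths, summary = summary_path))
}
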