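#' @rdname validate_records
#' @format NULL
#' @export
record_columns <- c(
  "record_id", "period", "hospital", "criticality", "pcne_cause",
  "intervention_group", "atc_category", "consequence_level", "ptc",
  "nesbit_category", "pcon_override", "implementation_status",
  "resolution_status", "dcs_avoided_cost", "dcs_added_cost",
  "intervention_time_minutes", "bed_day_cost"
)

#' Validate a table of clinical-pharmacy intervention records
#'
#' One row per intervention. Required columns (`record_columns`) carry the
#' model inputs: `criticality` stratum, PCNE cause label, intervention
#' group, ATC therapeutic category, consequence level 1–5, the probability
#' of trajectory change `ptc` (quartile-valued in {0, 0.25, 0.5, 0.75, 1}),
#' exactly one of `nesbit_category` (A–E) or an explicit `pcon_override`
#' probability, implementation and resolution statuses, the two signed
#' direct-cost-savings components (`dcs_avoided_cost`, `dcs_added_cost`,
#' both >= 0 EGP), intervention time in minutes (> 0) and the applicable
#' bed-day cost (> 0 EGP). An optional `patient_id` column supports
#' duplicate-intervention detection. Extra columns are preserved.
#'
#' @param records A data frame of intervention records.
#' @return The records as a tibble (invisibly validated); errors of class
#'   `dtp_validation_error` name offending rows.
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing record columns: ", paste(missing_cols, collapse = ", ")),
          class = "dtp_validation_error")
  }
  if (nrow(records) == 0) {
    abort("records table is empty", class = "dtp_validation_error")
  }
  if (anyDuplicated(records$record_id)) {
    abort("record_id values must be unique", class = "dtp_validation_error")
  }
  fail <- function(rows, msg) {
    if (any(rows)) {
      abort(sprintf("%s (rows %s)", msg,
                    paste(utils::head(which(rows), 5), collapse = ", ")),
            class = "dtp_validation_error")
    }
  }
  fail(is.na(records$period) | records$period < 1 |
         records$period != floor(records$period),
       "period must be an integer month index >= 1")
  fail(!records$criticality %in% .criticality_levels,
       "criticality must be critical/non_critical")
  fail(!records$consequence_level %in% 1:5, "consequence_level must be in 1..5")
  fail(is.na(records$ptc) | !vapply(records$ptc, function(p) any(abs(p - .ptc_levels) < 1e-12), logical(1)),
       "ptc must be one of 0, 0.25, 0.5, 0.75, 1")
  has_nesbit <- !is.na(records$nesbit_category)
  has_override <- !is.na(records$pcon_override)
  fail(has_nesbit == has_override,
       "exactly one of nesbit_category / pcon_override must be set")
  fail(has_nesbit & !records$nesbit_category %in% .nesbit_levels,
       "nesbit_category must be one of A..E")
  fail(has_override & (records$pcon_override < 0 | records$pcon_override > 1),
       "pcon_override must lie in [0, 1]")
  fail(!records$implementation_status %in% .impl_levels,
       "implementation_status must be implemented/not_implemented/unknown")
  fail(!records$resolution_status %in% .resol_levels,
       "resolution_status must be resolved/partially_resolved/unresolved/unknown")
  money <- cbind(records$dcs_avoided_cost, records$dcs_added_cost)
  fail(apply(!is.finite(money) | money < 0, 1, any),
       "DCS components must be finite and non-negative")
  fail(!is.finite(records$intervention_time_minutes) |
         records$intervention_time_minutes <= 0,
       "intervention_time_minutes must be positive")
  fail(!is.finite(records$bed_day_cost) | records$bed_day_cost <= 0,
       "bed_day_cost must be positive")
  records
}

#' Read / write intervention records
#'
#' The interchange dialect is UTF-8 comma-separated CSV with one column per
#' record field, lowercase enum tokens, `.` decimals and plain EGP amounts;
#' a JSON-lines file (`.jsonl`/`.ndjson`, one record object per line) with
#' identical field names is accepted interchangeably. Missing
#' `nesbit_category`/`pcon_override` entries are empty (CSV) or omitted
#' (JSONL).
#'
#' @param path Input or output file path; format chosen by extension.
#' @param records For `write_records()`, a valid records data frame.
#' @return `read_records()` returns a validated tibble; `write_records()`
#'   returns `path` invisibly.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort(paste0("records file not found: ", path), class = "dtp_io_error")
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    df <- as_tibble(df)
    for (col in c("nesbit_category", "pcon_override")) {
      if (!col %in% names(df)) df[[col]] <- NA
    }
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            record_id = readr::col_character(),
                            hospital = readr::col_character(),
                            nesbit_category = readr::col_character(),
                            pcon_override = readr::col_double(),
                            .default = readr::col_guess()
                          ))
  }
  df$period <- as.integer(df$period)
  df$consequence_level <- as.integer(df$consequence_level)
  df$pcon_override <- as.numeric(df$pcon_override)
  validate_records(df)
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(records), con, verbose = FALSE, digits = NA)
  } else {
    readr::write_csv(records, path, progress = FALSE)
  }
  invisible(path)
}

#' Validate ledgers used by the aggregate analytics
#'
#' The investment ledger has one row per `period` (month index) with
#' `fte_costs` (salaries, compensation, incentives, profit sharing) and
#' `non_fte_costs` (training, programs, medical wear, software, overheads),
#' both in EGP and non-negative; total investment over any analysed window
#' must be positive. The coverage ledger has one row per criticality
#' `stratum` with `covered_patient_days` and `total_patient_days`
#' (covered <= total, total > 0); a patient day is the service provided to
#' one patient over 24 hours.
#'
#' @param ledger A data frame.
#' @return The ledger as a validated tibble.
#' @export
validate_investment <- function(ledger) {
  ledger <- as_tibble(ledger)
  need <- c("period", "fte_costs", "non_fte_costs")
  if (!all(need %in% names(ledger))) {
    abort("investment ledger needs columns period, fte_costs, non_fte_costs",
          class = "dtp_validation_error")
  }
  amounts <- c(ledger$fte_costs, ledger$non_fte_costs)
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    abort("investment costs must be finite and non-negative",
          class = "dtp_validation_error")
  }
  ledger
}

#' @rdname validate_investment
#' @export
validate_coverage <- function(ledger) {
  ledger <- as_tibble(ledger)
  need <- c("stratum", "covered_patient_days", "total_patient_days")
  if (!all(need %in% names(ledger))) {
    abort("coverage ledger needs columns stratum, covered_patient_days, total_patient_days",
          class = "dtp_validation_error")
  }
  if (any(!ledger$stratum %in% .criticality_levels)) {
    abort("coverage stratum must be critical/non_critical", class = "dtp_validation_error")
  }
  if (any(ledger$total_patient_days <= 0)) {
    abort("total_patient_days must be positive", class = "dtp_validation_error")
  }
  if (any(ledger$covered_patient_days < 0 |
            ledger$covered_patient_days > ledger$total_patient_days)) {
    abort("covered_patient_days must lie in [0, total_patient_days]",
          class = "dtp_validation_error")
  }
  ledger
}
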