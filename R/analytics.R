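#' Total cost avoidance over a result set
#'
#' @param results A `dtp_avoidance` tibble (or any data frame with
#'   `gross_avoidance`/`net_avoidance` columns).
#' @param basis `"gross"` (before the pharmacist-arm cost) or `"net"`.
#' @return EGP.
#' @export
total_cost_avoidance <- function(results, basis = c("gross", "net")) {
  basis <- match.arg(basis)
  if (nrow(results) == 0) abort("empty result set", class = "dtp_validation_error")
  col <- paste0(basis, "_avoidance")
  sum(results[[col]])
}

#' Average cost avoidance per intervention
#'
#' @param total Total avoidance, EGP.
#' @param n Number of interventions (> 0).
#' @return EGP per intervention (full precision; reports round to whole EGP).
#' @export
average_per_intervention <- function(total, n) {
  if (any(n <= 0)) abort("n must be positive", class = "dtp_validation_error")
  total / n
}

#' Acceptance and resolution rates
#'
#' Acceptance is the share of interventions implemented by physicians;
#' resolution is the share of drug-therapy problems resolved among accepted
#' (implemented) interventions. Under the default `policy = "known"`,
#' records with unknown status are excluded from both numerator and
#' denominator, so the rates describe known outcomes; `policy = "strict"`
#' keeps unknowns in the denominator.
#'
#' @param records A validated intervention-record data frame.
#' @param policy `"known"` (default) or `"strict"`.
#' @return Percent (0–100).
#' @export
acceptance_rate <- function(records, policy = c("known", "strict")) {
  policy <- match.arg(policy)
  records <- validate_records(records)
  denom <- if (policy == "known") {
    filter(records, .data$implementation_status != "unknown")
  } else {
    records
  }
  if (nrow(denom) == 0) abort("no records in acceptance denominator",
                              class = "dtp_validation_error")
  100 * mean(denom$implementation_status == "implemented")
}

#' @rdname acceptance_rate
#' @export
resolution_rate <- function(records, policy = c("known", "strict")) {
  policy <- match.arg(policy)
  records <- validate_records(records)
  accepted <- filter(records, .data$implementation_status == "implemented")
  denom <- if (policy == "known") {
    filter(accepted, .data$resolution_status != "unknown")
  } else {
    accepted
  }
  if (nrow(denom) == 0) abort("no records in resolution denominator",
                              class = "dtp_validation_error")
  100 * mean(denom$resolution_status == "resolved")
}

#' Pool stratum rates into an overall rate
#'
#' Count-weighted mean, the identity linking stratum-level and overall
#' rates: the overall acceptance rate is the intervention-count-weighted
#' mean of stratum acceptance rates, and the overall resolution rate the
#' accepted-count-weighted mean of stratum resolution rates.
#'
#' @param rates Numeric vector of stratum rates (percent).
#' @param counts Corresponding denominators (> 0).
#' @return Pooled percent.
#' @export
pool_rate <- function(rates, counts) {
  if (length(rates) != length(counts) || any(counts <= 0)) {
    abort("rates and positive counts of equal length required",
          class = "dtp_validation_error")
  }
  weighted.mean(rates, counts)
}

#' Patient-day coverage
#'
#' `coverage = 100 x covered patient days / total patient days`, overall
#' and per criticality stratum.
#'
#' @param ledger A coverage ledger (see [validate_coverage()]).
#' @return A tibble with rows per stratum plus an `overall` row, columns
#'   `stratum`, `covered_patient_days`, `total_patient_days`,
#'   `coverage_pct`.
#' @export
coverage <- function(ledger) {
  ledger <- validate_coverage(ledger)
  per <- ledger %>%
    group_by(.data$stratum) %>%
    summarise(covered_patient_days = sum(.data$covered_patient_days),
              total_patient_days = sum(.data$total_patient_days),
              .groups = "drop")
  overall <- summarise(per,
    stratum = "overall",
    covered_patient_days = sum(.data$covered_patient_days),
    total_patient_days = sum(.data$total_patient_days)
  )
  bind_rows(per, overall) %>%
    mutate(coverage_pct = 100 * .data$covered_patient_days / .data$total_patient_days)
}

#' Return on investment of the clinical pharmacy service
#'
#' `ROI = (sum gross avoidance - sum investment) / sum investment` over a
#' period window. The numerator uses gross avoidance — pharmacist time is
#' not subtracted per record because FTE salaries already sit inside the
#' investment denominator; `basis = "net"` is available for sensitivity
#' analyses.
#'
#' @param results A `dtp_avoidance` tibble; must carry the originating
#'   `period` via `periods` (a vector aligned with `results`) or use
#'   [roi_series()] for the yearly breakdown.
#' @param investment An investment ledger (see [validate_investment()]).
#' @param basis `"gross"` (default) or `"net"`.
#' @return ROI as a ratio (0.5 means a 50% return over investment).
#' @export
roi <- function(results, investment, basis = c("gross", "net")) {
  basis <- match.arg(basis)
  investment <- validate_investment(investment)
  total_inv <- sum(investment$fte_costs + investment$non_fte_costs)
  if (total_inv <= 0) abort("total investment must be positive",
                            class = "dtp_validation_error")
  (total_cost_avoidance(results, basis) - total_inv) / total_inv
}

#' Yearly ROI series
#'
#' Maps month indices to calendar years (`period` 1 = January of
#' `start_year`) and computes the ROI within each calendar year; a partial
#' final year is reported as-is, not annualised.
#'
#' @param results A `dtp_avoidance` tibble.
#' @param periods Integer vector of month indices aligned with `results`
#'   rows (usually `records$period`).
#' @param investment An investment ledger with a `period` column.
#' @param start_year Calendar year of month index 1.
#' @param basis `"gross"` or `"net"`.
#' @return A tibble with `year`, `avoidance`, `investment`, `roi`.
#' @export
roi_series <- function(results, periods, investment, start_year = 2018,
                       basis = c("gross", "net")) {
  basis <- match.arg(basis)
  if (length(periods) != nrow(results)) {
    abort("periods must align with results rows", class = "dtp_validation_error")
  }
  investment <- validate_investment(investment)
  col <- paste0(basis, "_avoidance")
  av <- tibble(year = start_year + (as.integer(periods) - 1L) %/% 12L,
               avoidance = results[[col]]) %>%
    group_by(.data$year) %>%
    summarise(avoidance = sum(.data$avoidance), .groups = "drop")
  inv <- investment %>%
    mutate(year = start_year + (as.integer(.data$period) - 1L) %/% 12L) %>%
    group_by(.data$year) %>%
    summarise(investment = sum(.data$fte_costs + .data$non_fte_costs),
              .groups = "drop")
  out <- left_join(av, inv, by = "year")
  if (any(is.na(out$investment) | out$investment <= 0)) {
    abort("every year with avoidance needs positive investment",
          class = "dtp_validation_error")
  }
  mutate(out, roi = (.data$avoidance - .data$investment) / .data$investment)
}

#' Percentage impact of the panel costing scenario
#'
#' Signed percent change in total cost avoidance when moving from the fixed
#' literature consequence-day assumption to the severity/criticality panel
#' table.
#'
#' @param total_cleo Total under the panel method, EGP.
#' @param total_lit Total under the literature method, EGP (non-zero).
#' @return Signed percent.
#' @export
scenario_impact <- function(total_cleo, total_lit) {
  if (any(total_lit == 0)) abort("literature-scenario baseline must be non-zero",
                                 class = "dtp_validation_error")
  100 * (total_cleo - total_lit) / total_lit
}

#' Annualised cost avoidance
#'
#' @param total Total EGP over the window.
#' @param window_months Window length in months (> 0).
#' @return EGP per year.
#' @export
annualize <- function(total, window_months) {
  if (any(window_months <= 0)) abort("window_months must be positive",
                                     class = "dtp_validation_error")
  total * 12 / window_months
}

#' Convert EGP to USD at the configured display rate
#'
#' @param egp Amount in EGP.
#' @param params A `dtp_params` object (or a positive numeric rate).
#' @return USD.
#' @export
to_usd <- function(egp, params = model_parameters()) {
  rate <- if (is.numeric(params)) params else params$exchange_rate_egp_per_usd
  if (any(rate <= 0)) abort("exchange rate must be positive",
                            class = "dtp_validation_error")
  egp / rate
}
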