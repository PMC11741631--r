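#' Grouped breakdown report
#'
#' Aggregates per-record avoidance into one row per group of the chosen
#' key — criticality stratum, PCNE cause, intervention group, ATC
#' therapeutic category, or period — with the intervention count, gross and
#' net avoidance totals in EGP and USD, the group's share of interventions
#' and of avoidance (both sum to 100%), and the group's acceptance and
#' resolution rates. Rows are sorted by avoidance, descending. With
#' `top_n`, smaller groups collapse into an `"other"` residual row so that
#' shares still sum to 100%.
#'
#' @param results A `dtp_avoidance` tibble from [cost_avoidance()].
#' @param records The record table the results were computed from.
#' @param by Grouping key: one of `criticality`, `pcne_cause`,
#'   `intervention_group`, `atc_category`, `period`.
#' @param basis `"gross"` or `"net"` avoidance for the totals/shares.
#' @param params A `dtp_params` object (for the USD display rate).
#' @param top_n Optional number of leading groups to keep before the
#'   residual row.
#' @param rate_policy Passed to [acceptance_rate()]/[resolution_rate()].
#' @return A tibble of class `dtp_report` with columns `group`, `n`,
#'   `avoidance_egp`, `avoidance_usd`, `share_count_pct`,
#'   `share_avoidance_pct`, `acceptance_pct`, `resolution_pct`.
#' @export
grouped_report <- function(results, records, by, basis = c("gross", "net"),
                           params = model_parameters(), top_n = NULL,
                           rate_policy = c("known", "strict")) {
  basis <- match.arg(basis)
  rate_policy <- match.arg(rate_policy)
  keys <- c("criticality", "pcne_cause", "intervention_group",
            "atc_category", "period")
  if (length(by) != 1 || !by %in% keys) {
    abort(paste0("grouping key must be one of: ", paste(keys, collapse = ", ")),
          class = "dtp_validation_error")
  }
  records <- validate_records(records)
  col <- paste0(basis, "_avoidance")
  joined <- records %>%
    select(all_of(c("record_id", by, "implementation_status", "resolution_status"))) %>%
    left_join(select(tidy_results(results), all_of(c("record_id", col))),
              by = "record_id")
  if (any(is.na(joined[[col]]))) {
    abort("results and records do not match by record_id",
          class = "dtp_validation_error")
  }
  safe_rate <- function(df, fn) {
    tryCatch(fn(df, policy = rate_policy), error = function(e) NA_real_)
  }
  per_group <- function(df) {
    tibble(
      n = nrow(df),
      avoidance_egp = sum(df[[col]]),
      acceptance_pct = safe_rate(make_rate_stub(df), acceptance_rate),
      resolution_pct = safe_rate(make_rate_stub(df), resolution_rate)
    )
  }
  grp <- joined %>%
    rename(group = all_of(by)) %>%
    mutate(group = as.character(.data$group)) %>%
    tidyr::nest(data = -"group") %>%
    mutate(stats = purrr::map(.data$data, per_group)) %>%
    select("group", "stats") %>%
    tidyr::unnest("stats") %>%
    arrange(dplyr::desc(.data$avoidance_egp))
  if (!is.null(top_n) && nrow(grp) > top_n) {
    head_grp <- grp[seq_len(top_n), ]
    rest <- joined %>%
      rename(group = all_of(by)) %>%
      filter(!as.character(.data$group) %in% head_grp$group)
    other <- per_group(rest) %>% mutate(group = "other", .before = 1)
    grp <- bind_rows(head_grp, other)
  }
  total_av <- sum(grp$avoidance_egp)
  grp <- grp %>%
    mutate(
      avoidance_usd = to_usd(.data$avoidance_egp, params),
      share_count_pct = 100 * .data$n / sum(.data$n),
      share_avoidance_pct = if (total_av == 0) NA_real_ else 100 * .data$avoidance_egp / total_av
    ) %>%
    select("group", "n", "avoidance_egp", "avoidance_usd", "share_count_pct",
           "share_avoidance_pct", "acceptance_pct", "resolution_pct")
  structure(grp, class = c("dtp_report", class(grp)),
            by = by, basis = basis)
}

# rate helpers work on full record schemas; groups only carry the status
# columns, so rebuild a minimal valid record stub around them
make_rate_stub <- function(df) {
  tibble(
    record_id = paste0("s", seq_len(nrow(df))),
    period = 1L, hospital = "stub", criticality = "critical",
    pcne_cause = "stub", intervention_group = "stub", atc_category = "stub",
    consequence_level = 3L, ptc = 1, nesbit_category = "C",
    pcon_override = NA_real_,
    implementation_status = df$implementation_status,
    resolution_status = df$resolution_status,
    dcs_avoided_cost = 0, dcs_added_cost = 0,
    intervention_time_minutes = 1, bed_day_cost = 1
  )
}

tidy_results <- function(results) {
  out <- as_tibble(results)
  class(out) <- setdiff(class(out), c("dtp_avoidance", "dtp_report"))
  out
}

#' @export
print.dtp_report <- function(x, ...) {
  cat(sprintf("<dtp_report> by %s (%s avoidance)\n", attr(x, "by"), attr(x, "basis")))
  NextMethod()
}

#' Render a report with the publication's table precision
#'
#' EGP to whole units, EGP/USD millions and percentages to 2 decimals.
#' Internal arithmetic stays at full precision; rounding happens only here.
#'
#' @param report A `dtp_report` tibble.
#' @return A tibble with formatted columns.
#' @export
render_report <- function(report) {
  report %>%
    tidy_results() %>%
    mutate(
      avoidance_egp = round(.data$avoidance_egp),
      avoidance_usd = round(.data$avoidance_usd),
      avoidance_egp_millions = round(.data$avoidance_egp / 1e6, 2),
      avoidance_usd_millions = round(.data$avoidance_usd / 1e6, 2),
      across(dplyr::ends_with("_pct"), ~ round(.x, 2))
    )
}

#' Machine-readable summary of a full analysis
#'
#' Bundles every aggregate metric for a cohort: totals and averages under
#' both costing methods, the scenario impact, acceptance/resolution rates,
#' coverage, the yearly ROI series and cumulative ROI, and annualised
#' avoidance. This is the JSON-summary payload of the pipeline.
#'
#' @param records Validated intervention records.
#' @param investment Investment ledger.
#' @param coverage_ledger Coverage ledger.
#' @param params A `dtp_params` object.
#' @param start_year Calendar year of month index 1.
#' @return A nested list (JSON-ready).
#' @export
summarise_cohort <- function(records, investment, coverage_ledger,
                             params = model_parameters(), start_year = 2018) {
  records <- validate_records(records)
  res_cleo <- cost_avoidance(records, params, "cleo_panel")
  res_lit <- cost_avoidance(records, params, "lit")
  months <- max(records$period)
  tot_cleo <- total_cost_avoidance(res_cleo, "net")
  tot_lit <- total_cost_avoidance(res_lit, "net")
  cov <- coverage(coverage_ledger)
  series <- roi_series(res_cleo, records$period, investment, start_year)
  list(
    n_interventions = nrow(records),
    window_months = months,
    totals_egp = list(
      cleo_panel = list(gross = total_cost_avoidance(res_cleo, "gross"), net = tot_cleo),
      lit = list(gross = total_cost_avoidance(res_lit, "gross"), net = tot_lit)
    ),
    totals_usd = list(
      cleo_panel_net = to_usd(tot_cleo, params),
      lit_net = to_usd(tot_lit, params)
    ),
    average_per_intervention_egp = average_per_intervention(tot_cleo, nrow(records)),
    annualized_egp = annualize(tot_cleo, months),
    scenario_impact_pct = scenario_impact(tot_cleo, tot_lit),
    acceptance_pct = acceptance_rate(records),
    resolution_pct = resolution_rate(records),
    coverage = purrr::transpose(as.list(cov)),
    roi = list(
      cumulative = roi(res_cleo, investment),
      yearly = purrr::transpose(as.list(series))
    )
  )
}
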