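#' Cost of an adverse-consequence episode
#'
#' `cCON = consequence days x cost per consequence day`, where the cost per
#' day is the unit bed-day cost applicable to the patient's setting.
#'
#' @param days Consequence days (>= 0).
#' @param cost_per_day Bed-day cost in EGP (>= 0).
#' @return EGP.
#' @export
cost_of_consequence <- function(days, cost_per_day) {
  if (any(!is.finite(days)) || any(days < 0) ||
      any(!is.finite(cost_per_day)) || any(cost_per_day < 0)) {
    abort("days and cost_per_day must be finite and non-negative",
          class = "dtp_validation_error")
  }
  days * cost_per_day
}

#' Direct cost savings (DCS)
#'
#' Signed difference between the therapy/service costs avoided by the
#' intervention and the costs it added (new drugs, monitoring such as TDM
#' labs). Negative values are legitimate, e.g. for add-only interventions.
#'
#' @param avoided,added Non-negative EGP amounts.
#' @return Signed EGP.
#' @export
direct_cost_savings <- function(avoided, added) {
  if (any(!is.finite(avoided)) || any(avoided < 0) ||
      any(!is.finite(added)) || any(added < 0)) {
    abort("DCS components must be finite and non-negative",
          class = "dtp_validation_error")
  }
  avoided - added
}

#' Pharmacist-arm cost (cPharm)
#'
#' `cPharm = intervention time in minutes x FTE cost per minute`.
#'
#' @param minutes Intervention time (> 0).
#' @param fte_cost_per_minute EGP per minute (> 0).
#' @return EGP.
#' @export
pharmacist_cost <- function(minutes, fte_cost_per_minute) {
  if (any(!is.finite(minutes)) || any(minutes <= 0) ||
      any(!is.finite(fte_cost_per_minute)) || any(fte_cost_per_minute <= 0)) {
    abort("minutes and fte_cost_per_minute must be positive",
          class = "dtp_validation_error")
  }
  minutes * fte_cost_per_minute
}

#' Per-intervention cost avoidance
#'
#' Evaluates the extended cost-avoidance model for every record:
#'
#' \deqn{CA = pTC \times (pCON \times cCON + DCS) \times iFactor \times
#'   sFactor - cPharm}
#'
#' where `pCON` comes from the record's Nesbit category (or its explicit
#' override), `cCON` is consequence days (per the chosen costing method)
#' times the record's bed-day cost, `DCS` the signed direct cost savings,
#' and the two factors discount unimplemented/unresolved interventions.
#' The gross avoidance is the bracketed product; the net subtracts the
#' pharmacist-arm cost, and may be negative.
#'
#' With `params$factor_mode == "recomputed"` the unknown-status factor
#' constants are first re-derived from this cohort via
#' [recompute_factors()].
#'
#' @param records A validated intervention-record data frame.
#' @param params A `dtp_params` object.
#' @param method Consequence-day convention: severity/criticality panel
#'   (`"cleo_panel"`) or fixed literature days (`"lit"`).
#' @return A tibble of class `dtp_avoidance`, one row per record:
#'   `record_id`, `pcon`, `consequence_days`, `ccon`, `dcs`, `ifactor`,
#'   `sfactor`, `gross_avoidance`, `cpharm`, `net_avoidance`, `method`.
#'   The parameters and method used are attached as attributes; input
#'   grouping columns travel via [grouped_report()] joins, not here.
#' @examples
#' rec <- tibble::tibble(
#'   record_id = "r1", period = 1L, hospital = "H1",
#'   criticality = "critical", pcne_cause = "No indication of drug",
#'   intervention_group = "Drug paused or stopped",
#'   atc_category = "Antibacterial drugs", consequence_level = 4L,
#'   ptc = 1, nesbit_category = "B", pcon_override = NA_real_,
#'   implementation_status = "implemented", resolution_status = "resolved",
#'   dcs_avoided_cost = 1000, dcs_added_cost = 0,
#'   intervention_time_minutes = 20, bed_day_cost = 20000
#' )
#' cost_avoidance(rec, model_parameters())$net_avoidance  # 28900
#' @export
cost_avoidance <- function(records, params = model_parameters(),
                           method = c("cleo_panel", "lit")) {
  method <- match.arg(method)
  records <- validate_records(records)
  params <- validate_params(params)
  if (params$factor_mode == "recomputed") {
    params <- recompute_factors(records, params)
  }
  pcon <- ifelse(is.na(records$nesbit_category),
                 records$pcon_override,
                 nesbit_to_probability(records$nesbit_category, params))
  days <- consequence_days(records$consequence_level, records$criticality,
                           method, params)
  ccon <- cost_of_consequence(days, records$bed_day_cost)
  dcs <- direct_cost_savings(records$dcs_avoided_cost, records$dcs_added_cost)
  ifac <- implementation_factor(records$implementation_status, params)
  sfac <- status_factor(records$resolution_status, params)
  cpharm <- pharmacist_cost(records$intervention_time_minutes,
                            params$fte_cost_per_minute)
  gross <- records$ptc * (pcon * ccon + dcs) * ifac * sfac
  out <- tibble(
    record_id = records$record_id,
    pcon = pcon,
    consequence_days = days,
    ccon = ccon,
    dcs = dcs,
    ifactor = ifac,
    sfactor = sfac,
    gross_avoidance = gross,
    cpharm = cpharm,
    net_avoidance = gross - cpharm,
    method = method
  )
  if ("duplicate" %in% names(records)) out$duplicate <- records$duplicate
  structure(out,
            class = c("dtp_avoidance", class(out)),
            params = params, method = method)
}

#' @export
print.dtp_avoidance <- function(x, ...) {
  cat(sprintf("<dtp_avoidance> %d interventions, method = %s\n",
              nrow(x), attr(x, "method")))
  NextMethod()
}

#' Broom-style summaries of a cost-avoidance result
#'
#' `tidy()` returns the per-record decomposition as a plain tibble;
#' `glance()` a one-row summary with the intervention count, gross/net
#' totals (EGP and USD at the configured display rate), the mean net
#' avoidance per intervention and the total pharmacist-arm cost.
#'
#' @param x A `dtp_avoidance` object from [cost_avoidance()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dtp_avoidance
#' @export
tidy.dtp_avoidance <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dtp_avoidance")
  attr(out, "params") <- NULL
  attr(out, "method") <- NULL
  out
}

#' @rdname tidy.dtp_avoidance
#' @method glance dtp_avoidance
#' @export
glance.dtp_avoidance <- function(x, ...) {
  params <- attr(x, "params")
  rate <- params$exchange_rate_egp_per_usd
  tibble(
    n = nrow(x),
    method = attr(x, "method"),
    total_gross_egp = sum(x$gross_avoidance),
    total_net_egp = sum(x$net_avoidance),
    total_gross_usd = sum(x$gross_avoidance) / rate,
    total_net_usd = sum(x$net_avoidance) / rate,
    mean_net_egp = mean(x$net_avoidance),
    total_cpharm_egp = sum(x$cpharm)
  )
}
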