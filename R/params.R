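#' Model parameters for the cost-avoidance engine
#'
#' Bundles every constant of the extended cost-avoidance model: the Nesbit
#' probability map, the consequence-day tables for both costing methods, the
#' implementation/resolution factor constants, the pharmacist FTE cost per
#' minute, and the EGP/USD exchange rate used for display.
#'
#' The defaults are the published calibration of the model:
#' Nesbit A–E map to 60%, 40%, 10%, 1%, 0%; the severity panel assigns
#' 0/0/0.75/1.5/2.25 extra bed-days at consequence levels 1–5 for
#' non-critically ill patients and 0/0/1.5/3.5/5 for critically ill patients;
#' the literature method uses a fixed 2 consequence days at every level; the
#' implementation factor for unknown acceptance is 0.4129 and the status
#' factor for unknown resolution is 0.471 (0.5 for partial resolution).
#'
#' @param nesbit_map Named numeric vector mapping Nesbit categories `A`–`E`
#'   to consequence probabilities in `[0, 1]`, non-increasing from A to E.
#' @param cleo_day_table Data frame with columns `consequence_level` (1–5),
#'   `criticality` (`"non_critical"`/`"critical"`) and `days`; must be
#'   non-decreasing in level within each stratum, with critical days >=
#'   non-critical days at every level.
#' @param lit_fixed_days Fixed consequence days (> 0) used by the literature
#'   (`"lit"`) costing method regardless of level and criticality.
#' @param ifactor_unknown Implementation factor applied when acceptance of
#'   the intervention is unknown.
#' @param sfactor_unknown,sfactor_partial Status factors applied when the
#'   drug-therapy problem's resolution is unknown / partial.
#' @param fte_cost_per_minute Pharmacist full-time-equivalent cost, EGP per
#'   minute of intervention time (> 0).
#' @param exchange_rate_egp_per_usd EGP per USD used only to derive USD
#'   display values (> 0).
#' @param factor_mode `"fixed"` (default) uses the calibration constants
#'   above for unknown statuses; `"recomputed"` re-derives them from a
#'   cohort as half the empirical acceptance/resolution rates of records
#'   with known status (see [recompute_factors()]).
#' @return An object of class `dtp_params` (a named list).
#' @examples
#' p <- model_parameters()
#' nesbit_to_probability("A", p)
#' consequence_days(5, "non_critical", "cleo_panel", p)
#' @export
model_parameters <- function(nesbit_map = c(A = 0.60, B = 0.40, C = 0.10, D = 0.01, E = 0),
                             cleo_day_table = default_cleo_day_table(),
                             lit_fixed_days = 2,
                             ifactor_unknown = 0.4129,
                             sfactor_unknown = 0.471,
                             sfactor_partial = 0.5,
                             fte_cost_per_minute = 2.5,
                             exchange_rate_egp_per_usd = 30.85,
                             factor_mode = c("fixed", "recomputed")) {
  factor_mode <- match.arg(factor_mode)
  params <- structure(
    list(
      nesbit_map = nesbit_map,
      cleo_day_table = as_tibble(cleo_day_table),
      lit_fixed_days = lit_fixed_days,
      ifactor_unknown = ifactor_unknown,
      sfactor_unknown = sfactor_unknown,
      sfactor_partial = sfactor_partial,
      fte_cost_per_minute = fte_cost_per_minute,
      exchange_rate_egp_per_usd = exchange_rate_egp_per_usd,
      factor_mode = factor_mode
    ),
    class = "dtp_params"
  )
  validate_params(params)
}

#' Default severity-stratified consequence-day table
#'
#' Extra hospital days attributed to an unresolved drug-therapy problem, by
#' consequence level (1 insignificant ... 5 catastrophic) and patient
#' criticality, as set by the expert costing panel.
#'
#' @return A tibble with columns `consequence_level`, `criticality`, `days`.
#' @export
default_cleo_day_table <- function() {
  tibble(
    consequence_level = rep(1:5, times = 2),
    criticality = rep(c("non_critical", "critical"), each = 5),
    days = c(0, 0, 0.75, 1.5, 2.25, 0, 0, 1.5, 3.5, 5)
  )
}

validate_params <- function(params) {
  stopifnot(inherits(params, "dtp_params"))
  nm <- params$nesbit_map
  if (!identical(sort(names(nm)), sort(.nesbit_levels))) {
    abort("nesbit_map must be named with exactly the categories A-E")
  }
  nm <- nm[.nesbit_levels]
  if (any(!is.finite(nm)) || any(nm < 0) || any(nm > 1)) {
    abort("nesbit_map probabilities must lie in [0, 1]")
  }
  if (is.unsorted(rev(nm))) {
    abort("nesbit_map must be non-increasing from A to E")
  }
  tab <- params$cleo_day_table
  required <- c("consequence_level", "criticality", "days")
  if (!all(required %in% names(tab))) {
    abort("cleo_day_table needs columns consequence_level, criticality, days")
  }
  full <- tidyr::expand_grid(
    consequence_level = 1:5,
    criticality = .criticality_levels
  )
  if (nrow(dplyr::anti_join(full, tab, by = c("consequence_level", "criticality"))) > 0) {
    abort("cleo_day_table must cover all 5 levels for both criticality strata")
  }
  if (any(!is.finite(tab$days)) || any(tab$days < 0)) {
    abort("cleo_day_table days must be finite and non-negative")
  }
  wide <- tidyr::pivot_wider(tab,
    names_from = "criticality", values_from = "days",
    id_cols = "consequence_level"
  ) %>% arrange(.data$consequence_level)
  if (is.unsorted(wide$non_critical) || is.unsorted(wide$critical)) {
    abort("cleo_day_table days must be non-decreasing in consequence level")
  }
  if (any(wide$critical < wide$non_critical)) {
    abort("critical-stratum days must be >= non-critical days at every level")
  }
  scalars <- c(
    lit_fixed_days = params$lit_fixed_days,
    fte_cost_per_minute = params$fte_cost_per_minute,
    exchange_rate_egp_per_usd = params$exchange_rate_egp_per_usd
  )
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    abort("lit_fixed_days, fte_cost_per_minute and exchange_rate_egp_per_usd must be positive")
  }
  factors <- c(params$ifactor_unknown, params$sfactor_unknown, params$sfactor_partial)
  if (any(!is.finite(factors)) || any(factors < 0) || any(factors > 1)) {
    abort("factor constants must lie in [0, 1]")
  }
  params
}

#' @export
print.dtp_params <- function(x, ...) {
  cat("<dtp_params>\n")
  cat("  nesbit:", paste(sprintf("%s=%.2f", names(x$nesbit_map), x$nesbit_map), collapse = " "), "\n")
  cat("  lit_fixed_days:", x$lit_fixed_days,
      " ifactor_unknown:", x$ifactor_unknown,
      " sfactor_unknown:", x$sfactor_unknown, "\n")
  cat("  fte_cost_per_minute:", x$fte_cost_per_minute,
      "EGP/min  rate:", x$exchange_rate_egp_per_usd, "EGP/USD",
      " factor_mode:", x$factor_mode, "\n")
  invisible(x)
}

#' Read model parameters from a YAML or JSON configuration file
#'
#' Any omitted key falls back to the default calibration. `nesbit_map` may be
#' given as a mapping `{A: 0.6, ...}`; `cleo_day_table` as a list of rows
#' with `consequence_level`, `criticality`, `days`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `dtp_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path), class = "dtp_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$nesbit_map)) args$nesbit_map <- unlist(raw$nesbit_map)
  if (!is.null(raw$cleo_day_table)) {
    tab <- raw$cleo_day_table
    if (!is.data.frame(tab)) tab <- dplyr::bind_rows(lapply(tab, as_tibble))
    args$cleo_day_table <- tab
  }
  for (key in c("lit_fixed_days", "ifactor_unknown", "sfactor_unknown",
                "sfactor_partial", "fte_cost_per_minute",
                "exchange_rate_egp_per_usd", "factor_mode")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(model_parameters, args)
}

#' Write model parameters to a YAML configuration file
#'
#' @param params A `dtp_params` object.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- list(
    nesbit_map = as.list(params$nesbit_map),
    cleo_day_table = purrr::transpose(as.list(params$cleo_day_table)),
    lit_fixed_days = params$lit_fixed_days,
    ifactor_unknown = params$ifactor_unknown,
    sfactor_unknown = params$sfactor_unknown,
    sfactor_partial = params$sfactor_partial,
    fte_cost_per_minute = params$fte_cost_per_minute,
    exchange_rate_egp_per_usd = params$exchange_rate_egp_per_usd,
    factor_mode = params$factor_mode
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Map a Nesbit probability category to a consequence probability
#'
#' The Nesbit scale standardises expert likelihood judgements: A almost
#' certain (60%), B likely (40%), C possible (10%), D unlikely (1%),
#' E rare (0%).
#'
#' @param category Character vector of categories in `A`–`E`.
#' @param params A `dtp_params` object.
#' @return Numeric vector of probabilities.
#' @export
nesbit_to_probability <- function(category, params = model_parameters()) {
  bad <- setdiff(unique(category[!is.na(category)]), .nesbit_levels)
  if (length(bad) > 0) {
    abort(paste0("unknown Nesbit category: ", paste(bad, collapse = ", ")),
          class = "dtp_validation_error")
  }
  unname(params$nesbit_map[category])
}

#' Consequence days for a drug-therapy problem
#'
#' Under the `"cleo_panel"` method, returns the severity- and
#' criticality-stratified extra bed-days from the panel table; under `"lit"`
#' returns the fixed literature assumption (default 2 days) regardless of
#' level and criticality.
#'
#' @param level Integer vector of consequence levels in 1–5.
#' @param criticality `"critical"` or `"non_critical"` (recycled).
#' @param method `"cleo_panel"` or `"lit"`.
#' @param params A `dtp_params` object.
#' @return Numeric vector of days.
#' @export
consequence_days <- function(level, criticality, method = c("cleo_panel", "lit"),
                             params = model_parameters()) {
  method <- match.arg(method)
  if (any(is.na(level)) || any(!level %in% 1:5)) {
    abort("consequence level must be an integer in 1..5", class = "dtp_validation_error")
  }
  bad <- setdiff(unique(criticality), .criticality_levels)
  if (length(bad) > 0) {
    abort(paste0("unknown criticality: ", paste(bad, collapse = ", ")),
          class = "dtp_validation_error")
  }
  if (method == "lit") {
    return(rep_len(params$lit_fixed_days, max(length(level), length(criticality))))
  }
  key <- tibble(consequence_level = as.integer(level), criticality = criticality)
  left_join(key, params$cleo_day_table, by = c("consequence_level", "criticality"))$days
}

#' Implementation factor (iFactor)
#'
#' Encodes whether physicians implemented the recommendation: 1 when
#' implemented, 0 when not implemented, and a calibration constant
#' (default 0.4129) when acceptance is unknown.
#'
#' @param status Character vector in
#'   `implemented`/`not_implemented`/`unknown`.
#' @param params A `dtp_params` object.
#' @return Numeric factor in `[0, 1]`.
#' @export
implementation_factor <- function(status, params = model_parameters()) {
  bad <- setdiff(unique(status), .impl_levels)
  if (length(bad) > 0) {
    abort(paste0("unknown implementation status: ", paste(bad, collapse = ", ")),
          class = "dtp_validation_error")
  }
  map <- c(implemented = 1, not_implemented = 0, unknown = params$ifactor_unknown)
  unname(map[status])
}

#' Problem-status factor (sFactor)
#'
#' Encodes the final resolution of the drug-therapy problem: 1 resolved,
#' 0.5 partially resolved (configurable), 0 unresolved, and a calibration
#' constant (default 0.471) when the resolution is unknown.
#'
#' @param status Character vector in
#'   `resolved`/`partially_resolved`/`unresolved`/`unknown`.
#' @param params A `dtp_params` object.
#' @return Numeric factor in `[0, 1]`.
#' @export
status_factor <- function(status, params = model_parameters()) {
  bad <- setdiff(unique(status), .resol_levels)
  if (length(bad) > 0) {
    abort(paste0("unknown resolution status: ", paste(bad, collapse = ", ")),
          class = "dtp_validation_error")
  }
  map <- c(
    resolved = 1, partially_resolved = params$sfactor_partial,
    unresolved = 0, unknown = params$sfactor_unknown
  )
  unname(map[status])
}

#' Re-derive the unknown-status factors from a cohort
#'
#' Implements the `"recomputed"` factor mode: the unknown-implementation
#' factor becomes half the acceptance rate among records with known
#' acceptance, and the unknown-resolution factor half the resolution rate
#' among implemented records with known resolution — i.e. an unknown outcome
#' is valued at 50% of the empirically observed success rate.
#'
#' @param records An intervention-record data frame (see
#'   [validate_records()]).
#' @param params A `dtp_params` object whose constants are replaced.
#' @return A `dtp_params` object with updated `ifactor_unknown` and
#'   `sfactor_unknown`.
#' @export
recompute_factors <- function(records, params = model_parameters()) {
  records <- validate_records(records)
  known_impl <- filter(records, .data$implementation_status != "unknown")
  if (nrow(known_impl) == 0) abort("no records with known implementation status")
  acc <- mean(known_impl$implementation_status == "implemented")
  known_res <- filter(
    records,
    .data$implementation_status == "implemented",
    .data$resolution_status != "unknown"
  )
  if (nrow(known_res) == 0) abort("no implemented records with known resolution status")
  res <- mean(known_res$resolution_status == "resolved")
  params$ifactor_unknown <- 0.5 * acc
  params$sfactor_unknown <- 0.5 * res
  validate_params(params)
}
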