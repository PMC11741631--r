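default_cause_weights <- function() {
  c(
    "Condition without Treatment" = 26.2,
    "No indication of drug" = 23.8,
    "Inappropriate drug according to guidelines/formulary" = 11.8,
    "Dose too high" = 8.2,
    "Dose too low" = 7.5,
    "Dosage regimen too frequent" = 3.3,
    "Duration of treatment too long" = 3.1,
    "No or inappropriate outcome monitoring (incl. TDM)" = 2.9,
    "Inappropriate form/formulation" = 2.9,
    "Dosage regimen not frequent enough" = 2.7,
    "Inappropriate combination" = 2.4,
    "Inappropriate duplication of therapeutic group" = 2.1,
    "Dose timing instructions wrong, unclear or missing" = 1.3,
    "Other" = 1.8
  ) / 100
}

default_intervention_weights <- function() {
  w <- c(
    "Drug paused or stopped" = 40.7,
    "Drug Modified to a New Drug, Dose, Duration, or Form" = 26.8,
    "New drug added" = 24.1,
    "New Lab, service requested" = 8.2,
    "Instructions for use Added/changed" = 0.3
  )
  w / sum(w)
}

default_atc_weights <- function() {
  c(
    "Antibacterial drugs" = 30.5,
    "Antithrombotic agents" = 10.1,
    "Blood substitutes, perfusion solutions, and TPN" = 9.2,
    "Antihypertensive drugs" = 8.0,
    "Vitamins and Minerals" = 7.2,
    "Drugs for acid-related disorders" = 5.4,
    "Lipid modifying agents" = 2.4,
    "Drugs used in diabetes" = 2.0,
    "Drugs for functional gastrointestinal disorders" = 1.6,
    "Antigout preparations" = 1.6,
    "Other" = 22.0
  ) / 100
}

#' Configuration of a synthetic intervention cohort
#'
#' Defines every marginal of the generator. The defaults emulate the
#' published study conditions: a 70-month window, a critical-stratum share
#' of 12,570/19,240, stratum acceptance probabilities 85.41%/75.92% and
#' resolution-given-accepted probabilities 88.15%/89.65%, and cause /
#' intervention-group / ATC category weights taken from the published
#' breakdown tables (with an `"Other"` residual so each vector sums to 1).
#' Cost and time marginals are not published per record; the defaults are
#' realistic right-skewed choices (log-normal intervention time with a
#' 10-minute median; uniform bed-day cost within stratum ranges; log-normal
#' direct-cost components with point masses at zero) and are all visible
#' and overridable here.
#'
#' @param n_records Number of interventions to draw (> 0).
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @param months Study-window length in months.
#' @param critical_fraction Probability a record is critically ill.
#' @param consequence_level_distribution Named list with `critical` and
#'   `non_critical` probability vectors over levels 1–5.
#' @param nesbit_distribution Probability vector over categories A–E.
#' @param pcon_override_fraction Share of records whose consequence
#'   probability is an explicit literature-derived value instead of a
#'   Nesbit category.
#' @param ptc_distribution Probability vector over the trajectory-change
#'   quartiles 0, 0.25, 0.5, 0.75, 1.
#' @param acceptance_probability Named vector (`critical`, `non_critical`):
#'   probability the intervention is implemented.
#' @param resolution_probability Named vector: probability the problem is
#'   resolved given an implemented intervention.
#' @param partial_given_unresolved Probability an unresolved accepted
#'   problem is recorded as partially (rather than not) resolved.
#' @param unknown_status_fraction Probability that each status field is
#'   masked to `unknown`, injected independently of the latent draw.
#' @param cause_weights,intervention_weights,atc_weights Named probability
#'   vectors over the categorical vocabularies.
#' @param bed_day_cost_range Named list of `c(min, max)` EGP per stratum.
#' @param dcs_avoided,dcs_added Lists `list(zero_prob, meanlog, sdlog)` for
#'   the zero-inflated log-normal direct-cost components.
#' @param time_meanlog,time_sdlog Log-normal parameters of intervention
#'   time in minutes (defaults give a 10-minute median).
#' @param fte_cost_per_minute Pharmacist FTE cost, EGP/minute.
#' @param monthly_fte_investment,monthly_non_fte_investment Lists
#'   `list(meanlog, sdlog)` for the log-normal monthly investment draws.
#' @param patient_days_per_month Named vector of total patient days per
#'   month per stratum.
#' @param coverage_fraction Named vector of the patient-day coverage per
#'   stratum (critical areas get full coverage by default).
#' @param n_hospitals Number of site labels.
#' @return An object of class `dtp_cohort_config`.
#' @export
cohort_config <- function(
    n_records = 1000,
    seed = 1,
    months = 70,
    critical_fraction = 12570 / 19240,
    consequence_level_distribution = list(
      critical = c(0.08, 0.17, 0.35, 0.25, 0.15),
      non_critical = c(0.25, 0.30, 0.30, 0.12, 0.03)
    ),
    nesbit_distribution = c(A = 0.15, B = 0.30, C = 0.35, D = 0.15, E = 0.05),
    pcon_override_fraction = 0.10,
    ptc_distribution = c(0.02, 0.05, 0.13, 0.20, 0.60),
    acceptance_probability = c(critical = 0.8541, non_critical = 0.7592),
    resolution_probability = c(critical = 0.8815, non_critical = 0.8965),
    partial_given_unresolved = 0.4,
    unknown_status_fraction = 0.05,
    cause_weights = default_cause_weights(),
    intervention_weights = default_intervention_weights(),
    atc_weights = default_atc_weights(),
    bed_day_cost_range = list(critical = c(8000, 25000), non_critical = c(2000, 8000)),
    dcs_avoided = list(zero_prob = 0.25, meanlog = log(1500), sdlog = 1),
    dcs_added = list(zero_prob = 0.60, meanlog = log(400), sdlog = 1),
    time_meanlog = log(10),
    time_sdlog = 0.5,
    fte_cost_per_minute = 2.5,
    monthly_fte_investment = list(meanlog = log(450000), sdlog = 0.1),
    monthly_non_fte_investment = list(meanlog = log(90000), sdlog = 0.2),
    patient_days_per_month = c(critical = 1600, non_critical = 5400),
    coverage_fraction = c(critical = 1, non_critical = 0.6611),
    n_hospitals = 4) {
  cfg <- structure(as.list(environment()), class = "dtp_cohort_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "dtp_cohort_config"))
  if (cfg$n_records < 1) abort("n_records must be positive", class = "dtp_validation_error")
  if (cfg$months < 1) abort("months must be >= 1", class = "dtp_validation_error")
  check_pvec <- function(p, name, len = NULL) {
    if (!is.null(len) && length(p) != len) {
      abort(sprintf("%s must have %d entries", name, len), class = "dtp_validation_error")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("%s must be a probability vector summing to 1", name),
            class = "dtp_validation_error")
    }
  }
  check_pvec(cfg$consequence_level_distribution$critical, "level distribution (critical)", 5)
  check_pvec(cfg$consequence_level_distribution$non_critical, "level distribution (non_critical)", 5)
  check_pvec(cfg$nesbit_distribution, "nesbit_distribution", 5)
  check_pvec(cfg$ptc_distribution, "ptc_distribution", 5)
  check_pvec(cfg$cause_weights, "cause_weights")
  check_pvec(cfg$intervention_weights, "intervention_weights")
  check_pvec(cfg$atc_weights, "atc_weights")
  probs <- c(cfg$critical_fraction, cfg$pcon_override_fraction,
             cfg$acceptance_probability, cfg$resolution_probability,
             cfg$partial_given_unresolved, cfg$unknown_status_fraction,
             cfg$coverage_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("all probability scalars must lie in [0, 1]", class = "dtp_validation_error")
  }
  cfg
}

#' Study-conditions cohort configuration
#'
#' The default configuration whose marginals match the published strata:
#' critical fraction 12,570/19,240, stratum acceptance 85.41%/75.92%,
#' resolution-given-accepted 88.15%/89.65%, and the published cause /
#' intervention / ATC category shares, scaled to a requested cohort size.
#'
#' @param n_records Cohort size (default the published 19,240).
#' @param seed RNG seed.
#' @param ... Overrides forwarded to [cohort_config()].
#' @return A `dtp_cohort_config`.
#' @export
paperlike_config <- function(n_records = 19240, seed = 1, ...) {
  cohort_config(n_records = n_records, seed = seed, ...)
}

sample_zilnorm <- function(n, spec) {
  zero <- runif(n) < spec$zero_prob
  ifelse(zero, 0, rlnorm(n, spec$meanlog, spec$sdlog))
}

#' Generate a synthetic intervention cohort with its ledgers
#'
#' Draws `n_records` intervention records, a monthly investment ledger and
#' a per-stratum coverage ledger from the marginals in `config`,
#' deterministically for a fixed seed. Statuses are drawn in two stages: a
#' latent accept/resolve outcome at the configured stratum probabilities,
#' then independent masking to `unknown` at `unknown_status_fraction` — so
#' rates computed on known-status records recover the configured
#' probabilities, and the recomputed factor mode has a well-defined truth.
#'
#' @param config A `dtp_cohort_config`.
#' @return A list with elements `records` (validated record tibble,
#'   including a `patient_id` column), `investment`, `coverage`
#'   (ledger tibbles), `bookkeeping` (exact sampled counts by stratum,
#'   status and category, for oracle checks) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_config(config)
  set.seed(config$seed)
  n <- config$n_records

  criticality <- ifelse(runif(n) < config$critical_fraction, "critical", "non_critical")
  level <- integer(n)
  for (s in .criticality_levels) {
    idx <- criticality == s
    if (any(idx)) {
      level[idx] <- sample(1:5, sum(idx), replace = TRUE,
                           prob = config$consequence_level_distribution[[s]])
    }
  }
  use_override <- runif(n) < config$pcon_override_fraction
  nesbit <- ifelse(use_override, NA_character_,
                   sample(.nesbit_levels, n, replace = TRUE,
                          prob = config$nesbit_distribution))
  override <- ifelse(use_override, runif(n, 0, 0.8), NA_real_)
  ptc <- sample(.ptc_levels, n, replace = TRUE, prob = config$ptc_distribution)

  latent_accept <- runif(n) < config$acceptance_probability[criticality]
  latent_resolve <- runif(n) < config$resolution_probability[criticality]
  impl <- ifelse(latent_accept, "implemented", "not_implemented")
  resol <- ifelse(!latent_accept, "unresolved",
                  ifelse(latent_resolve, "resolved",
                         ifelse(runif(n) < config$partial_given_unresolved,
                                "partially_resolved", "unresolved")))
  impl[runif(n) < config$unknown_status_fraction] <- "unknown"
  resol[runif(n) < config$unknown_status_fraction] <- "unknown"

  bed_lo <- vapply(config$bed_day_cost_range[criticality], `[`, numeric(1), 1)
  bed_hi <- vapply(config$bed_day_cost_range[criticality], `[`, numeric(1), 2)

  records <- tibble(
    record_id = sprintf("r%06d", seq_len(n)),
    patient_id = sprintf("p%06d", sample.int(max(2 * n, 10), n, replace = FALSE)),
    period = sample.int(config$months, n, replace = TRUE),
    hospital = sample(paste0("H", seq_len(config$n_hospitals)), n, replace = TRUE),
    criticality = criticality,
    pcne_cause = sample(names(config$cause_weights), n, replace = TRUE,
                        prob = config$cause_weights),
    intervention_group = sample(names(config$intervention_weights), n,
                                replace = TRUE, prob = config$intervention_weights),
    atc_category = sample(names(config$atc_weights), n, replace = TRUE,
                          prob = config$atc_weights),
    consequence_level = level,
    ptc = ptc,
    nesbit_category = nesbit,
    pcon_override = override,
    implementation_status = impl,
    resolution_status = resol,
    dcs_avoided_cost = round(sample_zilnorm(n, config$dcs_avoided), 2),
    dcs_added_cost = round(sample_zilnorm(n, config$dcs_added), 2),
    intervention_time_minutes = round(rlnorm(n, config$time_meanlog, config$time_sdlog), 1),
    bed_day_cost = round(runif(n, bed_lo, bed_hi), 2)
  )
  records <- validate_records(records)

  investment <- tibble(
    period = seq_len(config$months),
    fte_costs = round(rlnorm(config$months, config$monthly_fte_investment$meanlog,
                             config$monthly_fte_investment$sdlog), 2),
    non_fte_costs = round(rlnorm(config$months, config$monthly_non_fte_investment$meanlog,
                                 config$monthly_non_fte_investment$sdlog), 2)
  )

  total_days <- config$patient_days_per_month * config$months
  coverage_ledger <- tibble(
    stratum = names(total_days),
    covered_patient_days = unname(total_days * config$coverage_fraction[names(total_days)]),
    total_patient_days = unname(total_days)
  )

  bookkeeping <- list(
    stratum = count(records, .data$criticality),
    implementation = count(records, .data$criticality, .data$implementation_status),
    resolution = count(
      filter(records, .data$implementation_status == "implemented"),
      .data$criticality, .data$resolution_status
    ),
    latent = tibble(
      criticality = criticality,
      latent_accept = latent_accept,
      latent_resolve = latent_resolve
    ) %>%
      group_by(.data$criticality) %>%
      summarise(n = n(),
                accepted = sum(.data$latent_accept),
                resolved_given_accepted = sum(.data$latent_accept & .data$latent_resolve),
                .groups = "drop"),
    cause = count(records, .data$pcne_cause),
    intervention_group = count(records, .data$intervention_group),
    atc = count(records, .data$atc_category)
  )

  list(records = records, investment = investment,
       coverage = coverage_ledger, bookkeeping = bookkeeping,
       config = config)
}
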