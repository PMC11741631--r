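# fixture builders shared across the suite

# one fully specified record; override any field by name
make_record <- function(...) {
  rec <- tibble::tibble(
    record_id = "r1",
    period = 1L,
    hospital = "H1",
    criticality = "critical",
    pcne_cause = "No indication of drug",
    intervention_group = "Drug paused or stopped",
    atc_category = "Antibacterial drugs",
    consequence_level = 4L,
    ptc = 1,
    nesbit_category = "B",
    pcon_override = NA_real_,
    implementation_status = "implemented",
    resolution_status = "resolved",
    dcs_avoided_cost = 1000,
    dcs_added_cost = 0,
    intervention_time_minutes = 20,
    bed_day_cost = 20000
  )
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

# random record table sampled directly here, independent of the package's
# cohort generator, for oracle-equivalence checks
random_records <- function(n, seed) {
  set.seed(seed)
  use_override <- runif(n) < 0.2
  tibble::tibble(
    record_id = paste0("x", seq_len(n)),
    period = sample.int(70, n, replace = TRUE),
    hospital = sample(paste0("H", 1:4), n, replace = TRUE),
    criticality = sample(c("critical", "non_critical"), n, replace = TRUE),
    pcne_cause = sample(c("a", "b", "c"), n, replace = TRUE),
    intervention_group = sample(c("g1", "g2"), n, replace = TRUE),
    atc_category = sample(c("t1", "t2", "t3"), n, replace = TRUE),
    consequence_level = sample(1:5, n, replace = TRUE),
    ptc = sample(c(0, 0.25, 0.5, 0.75, 1), n, replace = TRUE),
    nesbit_category = ifelse(use_override, NA_character_,
                             sample(c("A", "B", "C", "D", "E"), n, replace = TRUE)),
    pcon_override = ifelse(use_override, runif(n), NA_real_),
    implementation_status = sample(c("implemented", "not_implemented", "unknown"),
                                   n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    resolution_status = sample(c("resolved", "partially_resolved", "unresolved", "unknown"),
                               n, replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1)),
    dcs_avoided_cost = round(rlnorm(n, log(1000), 1), 2),
    dcs_added_cost = round(rlnorm(n, log(200), 1), 2) * rbinom(n, 1, 0.5),
    intervention_time_minutes = round(rlnorm(n, log(10), 0.5), 1),
    bed_day_cost = round(runif(n, 2000, 25000), 2)
  )
}

# single-expression brute-force evaluation of the cost-avoidance formula,
# with every constant written out literally; the independent oracle
brute_force_net <- function(r, fte_rate = 2.5,
                            ifactor_unknown = 0.4129,
                            sfactor_unknown = 0.471,
                            method = "cleo_panel") {
  day_table <- rbind(non_critical = c(0, 0, 0.75, 1.5, 2.25),
                     critical = c(0, 0, 1.5, 3.5, 5))
  vapply(seq_len(nrow(r)), function(i) {
    x <- r[i, ]
    pcon <- if (is.na(x$nesbit_category)) x$pcon_override else
      c(A = 0.60, B = 0.40, C = 0.10, D = 0.01, E = 0)[[x$nesbit_category]]
    days <- if (method == "lit") 2 else day_table[x$criticality, x$consequence_level]
    ifac <- c(implemented = 1, not_implemented = 0,
              unknown = ifactor_unknown)[[x$implementation_status]]
    sfac <- c(resolved = 1, partially_resolved = 0.5, unresolved = 0,
              unknown = sfactor_unknown)[[x$resolution_status]]
    x$ptc * (pcon * days * x$bed_day_cost +
               (x$dcs_avoided_cost - x$dcs_added_cost)) * ifac * sfac -
      x$intervention_time_minutes * fte_rate
  }, numeric(1))
}
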