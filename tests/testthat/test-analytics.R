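fake_results <- function(net, gross = net) {
  tibble::tibble(
    record_id = paste0("r", seq_along(net)),
    gross_avoidance = gross, net_avoidance = net
  )
}

test_that("totals and averages behave like sums and means", {
  res <- fake_results(c(100, -20))
  expect_equal(total_cost_avoidance(res, "net"), 80)
  expect_equal(total_cost_avoidance(fake_results(42), "net"), 42)
  expect_error(total_cost_avoidance(fake_results(numeric(0))),
               class = "dtp_validation_error")
  expect_equal(average_per_intervention(100, 4), 25)
  expect_equal(average_per_intervention(0, 5), 0)
  expect_error(average_per_intervention(10, 0), class = "dtp_validation_error")
})

test_that("acceptance and resolution rates respect the unknown-status policy", {
  recs <- dplyr::bind_rows(lapply(1:10, function(i) make_record(record_id = paste0("r", i))))
  recs$implementation_status <- c(rep("implemented", 6), rep("not_implemented", 2),
                                  rep("unknown", 2))
  recs$resolution_status <- c(rep("resolved", 4), "unresolved", "unknown",
                              rep("unresolved", 4))
  expect_equal(acceptance_rate(recs), 100 * 6 / 8)          # unknowns excluded
  expect_equal(acceptance_rate(recs, "strict"), 60)          # unknowns in denominator
  expect_equal(resolution_rate(recs), 100 * 4 / 5)           # among accepted, known
  expect_equal(resolution_rate(recs, "strict"), 100 * 4 / 6)
  all_unknown <- recs
  all_unknown$implementation_status <- "unknown"
  expect_error(acceptance_rate(all_unknown), class = "dtp_validation_error")
})

test_that("pooling stratum rates by counts reproduces the overall rates", {
  # acceptance: 75.92% of 6,670 and 85.41% of 12,570 pool to 82.12%
  expect_equal(round(pool_rate(c(75.92, 85.41), c(6670, 12570)), 2), 82.12)
  # resolution: stratum rates weighted by accepted counts pool to 88.63%
  accepted <- c(0.7592 * 6670, 0.8541 * 12570)
  expect_equal(round(pool_rate(c(89.65, 88.15), accepted), 2), 88.63)
  expect_error(pool_rate(c(50, 60), c(0, 10)), class = "dtp_validation_error")
})

test_that("coverage is the patient-day ratio per stratum and overall", {
  led <- tibble::tibble(
    stratum = c("critical", "non_critical"),
    covered_patient_days = c(100, 50),
    total_patient_days = c(100, 100)
  )
  cov <- coverage(led)
  expect_equal(cov$coverage_pct[cov$stratum == "critical"], 100)
  expect_equal(cov$coverage_pct[cov$stratum == "non_critical"], 50)
  expect_equal(cov$coverage_pct[cov$stratum == "overall"], 75)
  led$covered_patient_days[1] <- 150
  expect_error(coverage(led), class = "dtp_validation_error")
})

test_that("ROI satisfies its algebraic identity on random inputs", {
  set.seed(9)
  for (i in 1:20) {
    gross <- runif(50, -1000, 50000)
    inv <- tibble::tibble(period = 1:12,
                          fte_costs = runif(12, 1e4, 1e5),
                          non_fte_costs = runif(12, 1e3, 1e4))
    res <- fake_results(gross - 10, gross)
    r <- roi(res, inv)
    expect_equal(r + 1, sum(gross) / sum(inv$fte_costs + inv$non_fte_costs))
  }
  expect_equal(roi(fake_results(860, 860),
                   tibble::tibble(period = 1, fte_costs = 100, non_fte_costs = 0)),
               7.6)
  expect_equal(roi(fake_results(100, 100),
                   tibble::tibble(period = 1, fte_costs = 100, non_fte_costs = 0)),
               0)
  expect_error(roi(fake_results(1),
                   tibble::tibble(period = 1, fte_costs = 0, non_fte_costs = 0)),
               class = "dtp_validation_error")
})

test_that("the yearly ROI series maps months to calendar years", {
  res <- fake_results(rep(100, 24), rep(120, 24))
  periods <- rep(1:24, each = 1)
  inv <- tibble::tibble(period = 1:24, fte_costs = 500, non_fte_costs = 100)
  ser <- roi_series(res, periods, inv, start_year = 2018)
  expect_equal(ser$year, c(2018, 2019))
  expect_equal(ser$avoidance, c(12 * 120, 12 * 120))
  expect_equal(ser$roi, (12 * 120 - 12 * 600) / (12 * 600) + c(0, 0))
  # partial final year is reported as-is
  ser2 <- roi_series(fake_results(rep(10, 10), rep(10, 10)), 61:70,
                     tibble::tibble(period = 1:70, fte_costs = 10, non_fte_costs = 0),
                     start_year = 2018)
  expect_equal(max(ser2$year), 2023)
  expect_equal(ser2$investment[ser2$year == 2023], 100)  # 10 months only
})

test_that("scenario impact matches the published percent changes", {
  expect_equal(round(scenario_impact(265.32e6, 196.03e6), 2), 35.35)
  expect_equal(round(scenario_impact(251.36e6, 166.62e6), 2), 50.86)
  expect_equal(round(scenario_impact(13.96e6, 29.41e6), 2), -52.53)
  expect_equal(scenario_impact(5, 5), 0)
  expect_error(scenario_impact(1, 0), class = "dtp_validation_error")
})

test_that("annualisation scales a window total to a yearly rate", {
  expect_equal(annualize(12e6, 12), 12e6)
  expect_equal(annualize(6e6, 6), 12e6)
  # the 70-month grand total annualises to ~45.48M
  expect_equal(round(annualize(265.32e6, 70) / 1e6, 2), 45.48)
  expect_error(annualize(1, 0), class = "dtp_validation_error")
})

test_that("USD display values derive from the configured rate", {
  expect_equal(to_usd(30.85, model_parameters()), 1)
  expect_equal(to_usd(0, model_parameters()), 0)
  expect_equal(round(to_usd(265.32e6, model_parameters()) / 1e6, 2), 8.6)
  expect_error(to_usd(1, -2), class = "dtp_validation_error")
})

test_that("grouped reports are additive with shares summing to 100", {
  cohort <- generate_cohort(cohort_config(n_records = 600, seed = 21))
  recs <- cohort$records
  res <- cost_avoidance(recs, model_parameters())
  total <- total_cost_avoidance(res, "gross")
  for (key in c("criticality", "pcne_cause", "intervention_group", "atc_category")) {
    rep <- grouped_report(res, recs, key)
    expect_equal(sum(rep$n), nrow(recs))
    expect_equal(sum(rep$avoidance_egp), total)
    expect_equal(sum(rep$share_count_pct), 100)
    expect_equal(sum(rep$share_avoidance_pct), 100)
    expect_equal(rep$avoidance_usd * 30.85, rep$avoidance_egp)
    expect_false(is.unsorted(rev(rep$avoidance_egp)))
  }
  expect_error(grouped_report(res, recs, "hospital"), class = "dtp_validation_error")
})

test_that("truncated reports collapse the tail into an 'other' row", {
  cohort <- generate_cohort(cohort_config(n_records = 500, seed = 22))
  res <- cost_avoidance(cohort$records, model_parameters())
  rep <- grouped_report(res, cohort$records, "pcne_cause", top_n = 4)
  expect_equal(nrow(rep), 5)
  expect_equal(rep$group[5], "other")
  expect_equal(sum(rep$n), nrow(cohort$records))
  expect_equal(sum(rep$share_count_pct), 100)
  expect_equal(sum(rep$avoidance_egp), total_cost_avoidance(res, "gross"))
})

test_that("single-group and two-group shares behave proportionally", {
  recs <- dplyr::bind_rows(
    make_record(record_id = "a", pcne_cause = "c1", dcs_avoided_cost = 75),
    make_record(record_id = "b", pcne_cause = "c2", dcs_avoided_cost = 25,
                consequence_level = 4L)
  )
  recs$ptc <- 1
  recs$nesbit_category <- NA_character_
  recs$pcon_override <- 0  # isolate DCS so shares are exactly 75/25
  res <- cost_avoidance(recs, model_parameters())
  rep <- grouped_report(res, recs, "pcne_cause")
  expect_equal(rep$share_avoidance_pct, c(75, 25))
  one <- grouped_report(res[1, ], recs[1, ], "pcne_cause")
  expect_equal(one$share_avoidance_pct, 100)
})

test_that("monetary rescaling leaves rates, shares, ROI and impacts unchanged", {
  k <- 3.7
  cohort <- generate_cohort(cohort_config(n_records = 400, seed = 13))
  recs <- cohort$records
  inv <- cohort$investment
  p <- model_parameters()
  scaled <- recs
  scaled$dcs_avoided_cost <- scaled$dcs_avoided_cost * k
  scaled$dcs_added_cost <- scaled$dcs_added_cost * k
  scaled$bed_day_cost <- scaled$bed_day_cost * k
  p_scaled <- model_parameters(fte_cost_per_minute = p$fte_cost_per_minute * k)
  inv_scaled <- dplyr::mutate(inv, fte_costs = fte_costs * k,
                              non_fte_costs = non_fte_costs * k)
  res <- cost_avoidance(recs, p)
  res_k <- cost_avoidance(scaled, p_scaled)
  expect_equal(total_cost_avoidance(res_k, "net"),
               k * total_cost_avoidance(res, "net"))
  expect_equal(average_per_intervention(total_cost_avoidance(res_k, "net"), 400),
               k * average_per_intervention(total_cost_avoidance(res, "net"), 400))
  expect_equal(roi(res_k, inv_scaled), roi(res, inv))
  expect_equal(acceptance_rate(scaled), acceptance_rate(recs))
  expect_equal(resolution_rate(scaled), resolution_rate(recs))
  lit <- cost_avoidance(recs, p, "lit")
  lit_k <- cost_avoidance(scaled, p_scaled, "lit")
  expect_equal(
    scenario_impact(total_cost_avoidance(res_k, "net"), total_cost_avoidance(lit_k, "net")),
    scenario_impact(total_cost_avoidance(res, "net"), total_cost_avoidance(lit, "net"))
  )
  expect_equal(grouped_report(res_k, scaled, "criticality", params = p_scaled)$share_avoidance_pct,
               grouped_report(res, recs, "criticality", params = p)$share_avoidance_pct)
})
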