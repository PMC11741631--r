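test_that("records round-trip through CSV and JSON-lines identically", {
  recs <- generate_cohort(cohort_config(n_records = 60, seed = 14))$records
  csv <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, csv)
  back <- read_records(csv)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-12)
  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  write_records(recs, jsonl)
  back2 <- read_records(jsonl)
  expect_equal(as.data.frame(back2[record_columns]),
               as.data.frame(recs[record_columns]), tolerance = 1e-12)
  # a second write of the re-read table is byte-identical
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_records(back, csv2)
  expect_identical(readLines(csv), readLines(csv2))
})

test_that("ledgers round-trip and reject inconsistent rows", {
  inv <- tibble::tibble(period = 1:6, fte_costs = runif(6, 1e4, 1e5),
                        non_fte_costs = runif(6, 1e3, 1e4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_investment(inv, f)
  expect_equal(as.data.frame(read_investment(f)), as.data.frame(inv),
               tolerance = 1e-12)
  expect_error(validate_investment(dplyr::mutate(inv, fte_costs = -1)),
               class = "dtp_validation_error")
  cov <- tibble::tibble(stratum = c("critical", "non_critical"),
                        covered_patient_days = c(10, 5),
                        total_patient_days = c(10, 20))
  g <- withr::local_tempfile(fileext = ".csv")
  write_coverage(cov, g)
  expect_equal(as.data.frame(read_coverage(g)), as.data.frame(cov))
  expect_error(validate_coverage(dplyr::mutate(cov, covered_patient_days = 30)),
               class = "dtp_validation_error")
})

test_that("duplicate interventions are flagged and excluded from totals exactly", {
  recs <- generate_cohort(cohort_config(n_records = 80, seed = 31))$records
  flagged <- flag_duplicates(recs)
  expect_false(any(flagged$duplicate))  # distinct patients by construction
  # inject a same-patient/same-cause/same-period duplicate of row 10
  dup <- recs[10, ]
  dup$record_id <- "dup1"
  with_dup <- dplyr::bind_rows(recs, dup)
  flagged <- flag_duplicates(with_dup)
  expect_equal(sum(flagged$duplicate), 1)
  expect_true(flagged$duplicate[flagged$record_id == "dup1"])
  res <- cost_avoidance(flagged, model_parameters())
  kept <- dplyr::filter(res, !duplicate)
  # manual-exclusion oracle: totals drop by exactly the duplicate's value
  expect_equal(total_cost_avoidance(kept, "net"),
               total_cost_avoidance(res, "net") -
                 res$net_avoidance[res$record_id == "dup1"])
  expect_equal(total_cost_avoidance(kept, "net"),
               total_cost_avoidance(cost_avoidance(recs, model_parameters()), "net"))
})

test_that("the simulate/compute/report pipeline produces consistent files", {
  out <- withr::local_tempdir()
  sim <- cmd_simulate(file.path(out, "sim"), n_records = 120, seed = 8,
                      quiet = TRUE)
  expect_true(file.exists(sim$records))
  comp <- cmd_compute(sim$records, file.path(out, "res"), method = "both",
                      quiet = TRUE)
  expect_named(comp$paths, c("cleo_panel", "lit"))
  expect_equal(comp$n_duplicates_excluded, 0)
  res_cleo <- readr::read_csv(comp$paths$cleo_panel, show_col_types = FALSE)
  res_lit <- readr::read_csv(comp$paths$lit, show_col_types = FALSE)
  expect_equal(nrow(res_cleo), 120)  # row count preserved
  expect_equal(nrow(res_lit), 120)
  expect_equal(res_cleo$dcs, res_lit$dcs)  # methods differ only via ccon
  rep <- cmd_report(sim$records, sim$investment, sim$coverage,
                    file.path(out, "rep"), quiet = TRUE)
  expect_true(file.exists(rep$summary))
  s <- jsonlite::read_json(rep$summary, simplifyVector = TRUE)
  expect_equal(s$n_interventions, 120)
  # additivity of the emitted grouped numbers
  by_crit <- readr::read_csv(rep$paths$criticality, show_col_types = FALSE)
  expect_equal(sum(by_crit$n), 120)
  expect_equal(sum(by_crit$share_count_pct), 100, tolerance = 0.011)
  # ROI series spans the calendar years of the 70-month window
  expect_equal(s$roi$yearly$year, 2018:2023)
  # scenario impact consistent with the method totals it compares
  expect_equal(
    s$scenario_impact_pct,
    100 * (s$totals_egp$cleo_panel$net - s$totals_egp$lit$net) / s$totals_egp$lit$net
  )
  expect_equal(s$totals_usd$cleo_panel_net * 30.85, s$totals_egp$cleo_panel$net,
               tolerance = 1e-9)
})

test_that("repeated simulation with one seed writes byte-identical files", {
  out <- withr::local_tempdir()
  a <- cmd_simulate(file.path(out, "a"), n_records = 40, seed = 99, quiet = TRUE)
  b <- cmd_simulate(file.path(out, "b"), n_records = 40, seed = 99, quiet = TRUE)
  expect_identical(readLines(a$records), readLines(b$records))
  expect_identical(readLines(a$investment), readLines(b$investment))
})

test_that("the CLI honours its exit-code contract", {
  out <- withr::local_tempdir()
  expect_equal(suppressMessages(
    dtp_cli(c("simulate", "--n", "30", "--seed", "4", "--out",
              file.path(out, "sim"), "--quiet"))), 0L)
  expect_equal(suppressMessages(
    dtp_cli(c("compute", "--records", file.path(out, "sim", "records.csv"),
              "--out", file.path(out, "res"), "--method", "both", "--quiet"))), 0L)
  expect_equal(suppressMessages(
    dtp_cli(c("report",
              "--records", file.path(out, "sim", "records.csv"),
              "--investment", file.path(out, "sim", "investment.csv"),
              "--coverage", file.path(out, "sim", "coverage.csv"),
              "--out", file.path(out, "rep"), "--quiet"))), 0L)
  expect_true(file.exists(file.path(out, "rep", "summary.json")))
  # usage, validation and I/O failures are distinct
  usage_out <- capture.output(usage_code <- dtp_cli(character(0)))
  expect_equal(usage_code, 1L)
  expect_match(usage_out[1], "usage")
  expect_equal(suppressMessages(dtp_cli(c("compute", "--quiet"))), 2L)
  expect_equal(suppressMessages(
    dtp_cli(c("compute", "--records", file.path(out, "nope.csv"),
              "--out", out, "--quiet"))), 3L)
  expect_equal(suppressMessages(dtp_cli(c("simulate", "--bogus"))), 2L)
})

test_that("fixtures subcommand writes a valid n=50 cohort", {
  out <- withr::local_tempdir()
  expect_equal(suppressMessages(
    dtp_cli(c("fixtures", "--seed", "2", "--out", out, "--quiet"))), 0L)
  recs <- read_records(file.path(out, "records.csv"))
  expect_equal(nrow(recs), 50)
})

test_that("the committed synthetic fixture loads and recomputes deterministically", {
  dir <- system.file("extdata", "synthetic_cohort_n50", package = "dtpcost")
  recs <- read_records(file.path(dir, "records.csv"))
  expect_equal(nrow(recs), 50)
  # the fixture is the fixtures-command output for seed 2026
  regen <- generate_cohort(cohort_config(n_records = 50, seed = 2026))$records
  expect_equal(as.data.frame(recs), as.data.frame(regen), tolerance = 1e-12)
  s <- summarise_cohort(recs, read_investment(file.path(dir, "investment.csv")),
                        read_coverage(file.path(dir, "coverage.csv")))
  expect_equal(s$n_interventions, 50)
  expect_true(is.finite(s$roi$cumulative))
})
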