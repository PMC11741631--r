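Package: dtpcost
Title: Cost-Avoidance and Return-on-Investment Analytics for Clinical
    Pharmacy Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an extended Patanwala-style pharmacoeconomic model
    for valuing clinical pharmacy interventions on drug therapy problems
    (DTPs): per-intervention cost avoidance from the probability of
    trajectory change, Nesbit-scaled consequence probabilities,
    severity- and criticality-stratified consequence costs, direct cost
    savings, implementation and resolution factors, and pharmacist
    full-time-equivalent cost. Provides aggregate analytics (return on
    investment, patient-day coverage, acceptance and resolution rates,
    scenario comparison, annualisation, grouped breakdown reports), a
    configurable synthetic intervention-cohort generator, tidy CSV/JSON
    interchange, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
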