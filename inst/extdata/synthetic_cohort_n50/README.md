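# synthetic_cohort_n50

Synthetic example cohort (no real patient or hospital data): the output of

    dtpcost fixtures --seed 2026 --out inst/extdata/synthetic_cohort_n50

i.e. `generate_cohort(cohort_config(n_records = 50, seed = 2026))` written
through the package's own CSV writers. `records.csv` holds 50 intervention
records, `investment.csv` the 70 monthly investment rows, `coverage.csv`
the per-stratum patient-day coverage ledger.
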