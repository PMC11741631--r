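---
title: "Valuing clinical pharmacy interventions: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing clinical pharmacy interventions: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtpcost)
```

## The economic model

Clinical pharmacists who review medication orders intercept drug therapy
problems (DTPs) before they harm patients. Because the harm never happens,
its cost never appears in accounts; the economic value of the service must
be modelled. `dtpcost` values each intervention as

$$CA = p_{TC}\,\bigl(p_{CON}\,c_{CON} + DCS\bigr)\, i\, s \;-\; c_{Pharm},$$

an expected-harm calculation discounted by a chain of probabilities and
implementation factors:

* $p_{TC}$, the probability of trajectory change, asks: absent the
  clinical pharmacist, would anyone else (central pharmacy checks, the
  medical team) have caught the problem? It is quartile-valued
  ($0, 0.25, 0.5, 0.75, 1$), with 1 reserved for problems only a
  comprehensive clinical review would find.
* $p_{CON}$ is the probability that the adverse consequence materialises
  if the DTP stays unresolved. Where literature estimates exist (e.g.
  stress-ulcer incidence without indicated prophylaxis) they are entered
  directly per record (`pcon_override`); otherwise expert judgement is
  standardised on the Nesbit scale: A almost certain = 60%, B likely =
  40%, C possible = 10%, D unlikely = 1%, E rare = 0%. Each record carries
  exactly one of the two sources — a deliberate single-source-of-truth
  constraint, so precedence rules never arise.
* $c_{CON}$ monetises the consequence as extra hospital days times the
  bed-day cost of the patient's setting. Bed-day cost is a per-record
  field, not a global constant: intensive-care days in a tertiary centre
  and ward days in a district hospital differ severalfold.
* $DCS$ is the signed direct saving: therapy stopped or avoided minus
  therapy and monitoring added (including TDM laboratory work). Add-only
  interventions legitimately yield negative $DCS$.
* $i$ (implementation) and $s$ (status) discount recommendations that
  physicians did not implement (0), implemented with certainty (1), or
  whose fate is unknown (0.4129); and problems resolved (1), partially
  resolved (0.5), unresolved (0) or of unknown resolution (0.471).
* $c_{Pharm}$ charges the pharmacist's own time: intervention minutes
  times the full-time-equivalent (FTE) cost per minute.

Net avoidance may be negative — the model subtracts $c_{Pharm}$
unconditionally, and a zero factor collapses the whole bracket, leaving
$-c_{Pharm}$. We report such records as-is rather than clipping at zero;
they are the honest cost of rejected or futile recommendations.

## Consequence days: two costing conventions

`consequence_days()` supports two conventions. The literature convention
(`lit`) assigns a fixed 2 days to every consequence, regardless of
severity — common in published cost-avoidance studies and a useful
conservative baseline. The panel convention (`cleo_panel`) stratifies by
consequence level (1 insignificant … 5 catastrophic) and patient
criticality:

| Level | Non-critically ill | Critically ill |
|---|---|---|
| 1–2 | 0 | 0 |
| 3 | 0.75 | 1.5 |
| 4 | 1.5 | 3.5 |
| 5 | 2.25 | 5 |

Levels 1–2 deliberately carry zero consequence cost: minor problems do
not extend stays, though such records still incur $c_{Pharm}$ and may
carry $DCS$, so they are never excluded from the dataset. The table is
validated to be non-decreasing in level and to dominate row-wise in the
critical stratum. `scenario_impact()` quantifies the signed percent
change in totals when moving from `lit` to `cleo_panel`; severity
stratification raises critical-stratum totals (3.5–5 days vs 2) and
lowers non-critical ones (0–2.25 days vs 2).

## The unknown-status factors

The defaults 0.4129 and 0.471 are fixed calibration constants
(`factor_mode = "fixed"`), documented as half of historical acceptance
and resolution rates. Which historical rates they halve is not derivable
from their published values — notably they do not equal half of the
overall rates reported alongside them — so the package also offers
`factor_mode = "recomputed"`, which re-derives them from the cohort at
hand: half the acceptance rate among records with known implementation
status, and half the resolution rate among implemented records with
known resolution. Neither mode is asserted to be the original
computation; `fixed` is the default because it reproduces the published
constants exactly and keeps results independent of the analysed cohort.

## Rates, pooling and coverage

`acceptance_rate()` and `resolution_rate()` default to a *known-status*
policy: unknowns leave both numerator and denominator, so the rates
describe known outcomes. A `strict` policy that keeps unknowns in the
denominator is available and systematically lower. Overall rates are
count-weighted means of stratum rates (`pool_rate()`): acceptance pools
by intervention counts, resolution by accepted counts — the identity the
test suite checks against the published stratum table. Coverage is the
patient-day ratio per stratum and overall; its published overall value is
not recomputable without the unpublished patient-day denominators, so the
package implements the formula and asserts nothing about that figure.

## ROI

The published ROI formula's numerator sums the *gross* bracket without
per-record $c_{Pharm}$. We implement that literally: pharmacist salaries
already sit in the FTE component of the investment denominator, and
subtracting $c_{Pharm}$ per record as well would double-count pharmacist
time. A `basis = "net"` option exists for sensitivity analysis. The
yearly series maps month index 1 to January of `start_year` (default
2018) and reports a partial final year as-is, without annualising.
`annualize()` converts any window total to a 12-month rate.

## Duplicate interventions

Counting the same intervention twice for one patient inflates totals. The
registry's identifier scheme is site-specific, so `flag_duplicates()`
uses a declared convention: key `(hospital, patient_id, pcne_cause,
period)` when a patient surrogate is present, else
`(hospital, pcne_cause, period)`, overridable via `key_cols`. First
occurrence wins; later rows are flagged, excluded from totals by the
pipeline, and counted in its log output.

## The synthetic cohort generator

No real per-record hospital data are available, so `generate_cohort()`
draws cohorts whose *marginals* match the published study conditions:
a 70-month window, critical-stratum share 12,570/19,240, stratum
acceptance probabilities 85.41%/75.92%, resolution-given-accepted
88.15%/89.65%, and cause/intervention/ATC category weights taken from the
published breakdown tables with an explicit `"Other"` residual so each
vector sums to 1.

Where the study publishes no per-record quantity, the defaults are chosen
once as field-realistic and kept:

* intervention time: log-normal with a 10-minute median (`sdlog` 0.5) —
  strictly positive and right-skewed, as chart-review timings are;
* bed-day cost: uniform within stratum ranges, 8,000–25,000 EGP critical
  and 2,000–8,000 EGP non-critical, reflecting 2023 Egyptian private
  tertiary-care price-index magnitudes;
* direct-cost components: zero-inflated log-normals (avoided: 25% zeros,
  median 1,500 EGP; added: 60% zeros, median 400 EGP), since many
  interventions change no drug cost at all;
* FTE cost 2.5 EGP/minute; monthly investment log-normal around 450,000
  EGP FTE plus 90,000 EGP non-FTE;
* consequence levels skew higher in the critical stratum; 10% of records
  carry a literature-style explicit consequence probability instead of a
  Nesbit category; statuses are masked to `unknown` at 5% *independently*
  of the latent accept/resolve draw, so known-status rates remain
  unbiased estimates of the configured probabilities and the recomputed
  factor mode has a well-defined truth to recover.

Monetary amounts are rounded to the cent and times to 0.1 minute at
generation — the precision real registries record — which also makes the
CSV/JSON-lines interchange round-trip byte-exact.

What the generator does **not** emulate: joint dependencies (consequence
level vs cause, cost vs category) are unreported and sampled
independently; and the published grand totals (EGP 265.32M, cumulative
ROI 7.6) depend on unpublished per-record costs and are deliberately not
targeted. Passing tests therefore demonstrate correctness of the engine
and the distributional fidelity of the marginals, not that synthetic
totals reproduce the published ones.

## Numerical and interface choices

All arithmetic runs at double precision end to end; rounding happens only
in `render_report()` (whole EGP, millions and percentages to 2 decimals)
to match publication precision. Currency is EGP throughout; USD is a
derived display value at a configurable rate defaulting to 30.85 EGP/USD,
the ratio implied by the published EGP and USD grand totals (the source
cites central-bank rates without printing one). Validation errors carry
class `dtp_validation_error` with offending row numbers; the command-line
wrapper maps validation and I/O failures to distinct exit codes (2, 3).
Grouped reports carry both a count share and an avoidance share — the two
useful "percentage" readings of a breakdown table — and both sum to 100%
by construction, with a residual `"other"` row when reports are
truncated.

Test problem sizes are chosen to keep the suite fast while leaving
binomial standard errors tight enough to detect real defects: oracle
equivalence uses 1,000 random records against a single-expression
brute-force evaluation at $10^{-9}$ relative tolerance; parameter
recovery uses $n = 20{,}000$ with 3-standard-error bands; linear-scaling
checks use $n \in \{1000, 2000, 4000\}$.

## Limitations

The model is an expected-value calculation, not an inferential one: no
confidence intervals accompany rates or totals, matching its intended
use in service dashboards. Consequence days come from expert consensus;
users with local length-of-stay data should replace the panel table via
`model_parameters()`. The generator's independence assumptions mean
synthetic cohorts understate the correlation structure of real
registries, and results on them validate software behaviour, not
clinical-economic conclusions.
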