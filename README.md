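# claimlines

Line-of-therapy derivation and time-to-event outcomes for diffuse large
B-cell lymphoma (DLBCL) from administrative insurance claims.

Real-world oncology studies built on claims databases never observe "lines
of therapy" directly: they observe dated pharmacy fills, procedure codes,
enrollment spans, and death records. The treatment episode structure —
which drugs form a combination regimen, when a patient advanced to the next
line, which infusions were bridging before CAR T rather than a new line —
has to be *derived* by an algorithm whose window choices (30-day
combinations, 90-day restart gaps, salvage and bridging attribution)
materially change every downstream number. `claimlines` implements that
machinery as a tested, reusable pipeline for researchers who build or audit
such studies, together with a seedable synthetic claims generator so every
stage can be validated against known ground truth without any licensed
data.

## What the package computes

**LOT derivation.** First line (1L) starts with the first DLBCL-directed
therapy after the initial diagnosis (ICD-10-CM C83.3x); all therapies
initiated within 30 days of line start join the combination. A line
advances when

* a DLBCL-directed drug not in the current line's drug set is first
  observed more than 30 days after line start,
* a stem cell transplant (SCT) or CAR T infusion is observed, or
* the regimen is discontinued (last days-supply-aware exposure end) and
  re-initiated after a gap of more than 90 days.

Maintenance therapy (configurable list, default rituximab/lenalidomide),
salvage therapy within 90 days before SCT (attributed to the transplant
line), and bridging therapy between apheresis and 7 days before CAR T
infusion (attributed to the CAR T line) never advance the line. SCT and
CAR T lines are indexed on the transplant/infusion date. Corticosteroids
and radiotherapy are outside the algorithm.

**Cohort eligibility.** Confirmed diagnosis (one inpatient primary claim or
two outpatient claims ≥ 30 days apart), ≥ 365 days of continuous enrollment
before and ≥ 29 days after the index date, age ≥ 18, no clinical-trial code
within 6 months, no other hematologic malignancy within 12 months, plus —
for line-number subgroups — a 6-month pre-diagnosis washout and exclusion
of legacy ICD-9 200.7x codes. Every check is evaluated (no
short-circuiting) so attrition tables are exact.

**Regimen classification.** Each line maps to exactly one of 12 hierarchy
categories by first match: CAR T; SCT; pola + R-CHP; pola ± other; R-CHOP;
tafa ± other; R monotherapy; chemotherapy; R-squared; other targeted
(lenalidomide/ibrutinib/venetoclax/selinexor); immunotherapy;
chemoimmunotherapy.

**Outcomes.** Kaplan–Meier estimates of overall survival
(OS: index → death, censored at disenrollment or study end) and time to
next treatment or death (TTNT: index → min(next-line start, death)), with
complementary log-log confidence intervals, Brookmeyer–Crowley-style median
CIs, and fixed-horizon treatment failure rates
`100 × (1 − Ŝ(h))` at 12 and 24 months.

**Reporting.** Therapy distribution by calendar year, baseline
characteristics, bridging and post-CAR T tables — all counts below 5 masked
at a single rendering chokepoint.

## Worked example

```r
library(claimlines)

sim    <- simulation_config(n_patients = 300, seed = 42)
cohort <- simulate_cohort(sim)          # claims bundle + ground truth
res    <- run_pipeline(cohort$bundle)   # LOTs, eligibility, KM, reports

head(res$lots[, c("patient_id", "lot_number", "start_date", "core_drugs", "regimen")], 3)
#>   patient_id lot_number start_date                                         core_drugs regimen
#> 1     P00001          1 2020-05-14 cyclophosphamide;doxorubicin;rituximab;vincristine   rchop
#> 2     P00001          2 2020-06-14                  gemcitabine;oxaliplatin;rituximab chemoimmunotherapy
#> 3     P00002          1 2019-04-14 cyclophosphamide;doxorubicin;rituximab;vincristine   rchop

res$outcomes$lot1$os_median
#>     median   ci_low ci_high median_not_reached ci_high_not_reached   n
#> 1 64.62423 51.21971 85.8809              FALSE               FALSE 298

res$outcomes$lot1$failure_rates
#>   horizon_months     rate   ci_low  ci_high n_at_risk_at_horizon
#> 1             12 36.89238 31.56546 42.80355                  169
#> 2             24 51.54168 45.71054 57.65113                  117

res$reports$peri_cart$summary[c(1, 4, 7), ]
#>                             measure value display
#> 1                     cart_patients    22      22
#> 4                post_cart_patients     4      <5
#> 7 apheresis_to_infusion_median_days    35      35
```

The first-line median OS of 64.6 months (95% CI 51.2–85.9) estimates the
generator's 58.1-month exponential truth at this small n; the 12-month
failure rate of 36.9% is `100 × (1 − Ŝ(365.25 d))` on the TTNT curve; and
the post-CAR T cell of 4 patients renders as `<5` in every artifact.

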