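---
title: "Deriving lines of therapy from claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving lines of therapy from claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimlines)
```

`claimlines` turns dated insurance-claims events — pharmacy fills with days
supply, procedure codes for transplant, CAR T infusion and apheresis,
diagnosis codes, enrollment spans, death records — into treatment episodes
("lines of therapy", LOT) for diffuse large B-cell lymphoma, and estimates
time-to-event outcomes on them. This vignette is the package's own account
of the algorithm, its assumptions, the decisions taken where the rules were
genuinely open, and what the synthetic-data validation does and does not
show.

## The LOT algorithm

Claims carry day-level granularity only, so dates are whole calendar days
and every interval is closed on both endpoints unless stated otherwise.

1. **Anchor.** The first observed DLBCL diagnosis is the earliest medical
   claim carrying a C83.3x code in any position. Therapy events before it
   are excluded (with a warning), since pre-diagnosis exposures cannot
   belong to a DLBCL line.
2. **Combination window.** The first DLBCL-directed, non-corticosteroid
   therapy after diagnosis opens line 1; every drug *first initiated*
   within 30 days (inclusive) of line start joins the combination
   (`core_drugs`).
3. **Advancement.** A line closes at the earliest of:
   a drug absent from the line's working drug set first observed *strictly
   more* than 30 days after line start (`new_therapy`); an SCT
   (`sct_observed`); a CAR T infusion (`cart_observed`); or re-initiation
   of a current-line drug after all of the line's exposures have lapsed
   for strictly more than 90 days (`restart_gap`). Discontinuation is
   days-supply-aware: the gap is measured from the maximum
   `fill_date + days_supply` over the line's fills, the standard claims
   convention for exposure end.
4. **Exemptions.** Three therapy patterns never advance a line:
   * *Bridging* — drug events in `[apheresis, infusion − 7 days]` belong
     to the CAR T line (its start is the earliest bridging drug, its index
     the infusion date). Without an apheresis claim a fallback window of
     60 days before `infusion − 7` is used.
   * *Salvage* — a drug that would otherwise advance the line but starts
     within 90 days before an SCT belongs to the transplant line (index =
     transplant date).
   * *Maintenance* — a drug on the maintenance list (default rituximab,
     lenalidomide) re-initiated after a multi-agent line containing it,
     with no other DLBCL-directed drug starting within the following
     30 days, is annotated maintenance and stays on its line.
5. **Index dates.** A line's index is its start date, except SCT/CAR T
   lines, which are indexed on the transplant or infusion date — the
   anchor for eligibility windows and outcome clocks.

### Decisions where the rules are open

These points are not determined by the algorithm's verbal statement; the
package fixes them explicitly and tests pin each one.

* **Boundary operators.** "Within 30 days" is inclusive (day 30 joins the
  combination); ">30 days" and ">90 days" are strict (day 31 advances, a
  91-day gap restarts). The day-29/30/31 and day-89/90/91 boundaries are
  pinned by fixtures and by exhaustive comparison against an independent
  brute-force reference.
* **Same-day ties.** SCT and CAR T events process before drug events of
  the same day (the modality dominates: a same-day drug becomes part of
  the transplant line), and same-day drugs process alphabetically, making
  ledgers deterministic. Shuffling input rows never changes the output.
* **"New" drug.** A drug is new only if absent from the line's working
  drug set (core plus attributed salvage/bridging/maintenance names);
  re-exposure to a known drug advances only via the restart rule.
* **Salvage scope.** The salvage exemption applies to events that would
  otherwise *advance* the line — including a restart-gap trigger inside
  the window. A patient's first-ever therapy is not salvage even when a
  transplant follows within 90 days: it opens line 1 and the SCT advances.
* **Maintenance scope.** The "only exposure in its window" condition is
  operationalized as *no other DLBCL-directed non-corticosteroid drug of a
  different name within the next 30 days*. A literal "no other **new**
  drug" reading would annotate the rituximab of a fully restarted R-CHOP
  as maintenance and split the restart across two lines; the chosen
  reading keeps regimen restarts intact.
* **Advancement clock on modality lines.** The >30-day clock always runs
  from the line *start* (earliest bridging/salvage drug), not the index
  date. A consequence: therapy started shortly after a CAR T infusion
  whose line began with bridging weeks earlier advances immediately, which
  matches the construction of post-CAR T next-line cohorts.
* **Corticosteroids** are retained in the event ledger for reporting but
  never initiate, join, or advance a line, and are removed before regimen
  classification. Unknown drug codes are kept, flagged, and excluded from
  derivation rather than aborting a run.

## Eligibility

All checks are evaluated without short-circuiting so the reason list is
complete and attrition tables are exact. Month-denominated rules use fixed
day counts for determinism: 6 months = 183 days, 12 months = 365 days
(config-overridable). Window conventions: diagnosis confirmation and the
clinical-trial lookback include the index date ("before or on"); the
other-malignancy lookback is `[index − 365, index − 1]`, strictly before
the index (the rule's wording does not settle index-day inclusion; strict
exclusion is documented rather than asserted as intent). Age uses birth
year only (`index year − birth year`), the de-identified claims
convention; exact birth dates are typically absent. Enrollment spans
separated by at most `allowable_gap_days` (default 1 day, i.e. abutting)
merge into continuous coverage; the tolerance for administrative
micro-gaps is a config knob, not a claim about any particular database.
The washout and legacy ICD-9 exclusions apply to line-number subgroups
only (`subgroup_mode = "lot_number"`), not to CAR T / post-CAR T
treatment subgroups.

## Outcomes

OS runs from the line index to death, censored at the earliest of
disenrollment or study end; TTNT is the composite of next-line start and
death. Estimation is the product-limit method via `survival::survfit`
(same-day ties grouped; events precede censorings at a tied time;
zero-duration events retained at t = 0), with complementary log-log
pointwise intervals. Medians invert those bands
(Brookmeyer–Crowley-style); a median or bound the curve never reaches is
reported as a distinct not-reached flag, never as a numeric infinity.
Fixed-horizon failure rates are `100 × (1 − Ŝ(h))` with the interval from
the same transform; a horizon beyond the last observed time with subjects
still at risk reports the last estimable time with a warning, and a
horizon with no events yet yields 0% with lower bound 0. Months use a
fixed 30.4375-day month (365.25 / 12); the conversion is configurable
since no single convention is universal. The complementary log-log choice
is a documented convention, standard for bounds on [0, 1] survival.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be tested against
known truth. Each patient draws an independent RNG stream derived from the
master seed and patient index, so enlarging a cohort never perturbs
earlier patients and equal seeds reproduce bundles byte-for-byte.

A *trajectory template* plans a sequence of lines (drug sets, start-offset
and stagger distributions, SCT/CAR T structure with apheresis lead time
and bridging drugs, maintenance segments, restart gaps). The default
mixture emulates contemporary DLBCL practice: R-CHOP-based first-line
therapy for 65% of patients (half with inpatient diagnosis confirmation,
a smaller arm confirmed by outpatient encounter pairs), rituximab
maintenance (10%), platinum salvage followed by autologous SCT (10%),
CAR T with pola + rituximab bridging and a 33-day apheresis-to-infusion
lead (10%), and an R-CHOP discontinuation/restart pattern (5%).

Survival uses exponential distributions by inverse CDF at day resolution:
OS median 58.1 months from the first-line index and composite TTNT median
36.1 months by default — values typical of contemporary first-line claims
cohorts. The progression hazard is the *difference* of the TTNT and OS
exponential rates, so the composite endpoint is exponential with the
stated median and progression never outlives death by construction; this
dependence structure is an assumption, not an estimate. Survival-driven
next lines start no earlier than 31 days after the prior line start (the
earliest advancement the algorithm can recognize); this clips only the
lowest ~1% of progression times and leaves the composite's survival
function unchanged from day 31 onward. Enrollment churn is exponential
(default monthly hazard 0.01, roughly 11% annual turnover); enrollment is
administrative coverage and may extend past death, which avoids an
immortal-time interaction with the 29-day post-index rule that the
eligibility rules do not themselves address. Claims are emitted only up to
the patient's data horizon (death, disenrollment, study end); ground truth
is computed from the *realized* schedule, so truth and claims stay
consistent under truncation, and therapy on a line stops at progression so
lines never interleave.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: real drug-code vocabularies (codes are
synthetic strings declared in the shipped dictionary); inpatient drug
detail hidden behind generic administration codes; conditioning
chemotherapy in the week before CAR T infusion; radiotherapy; coding
errors and duplicate claims; dependence between survival and regimen
choice; and real marginal demographics. Recovery tests demonstrate that
the engine inverts the generator's (deliberately engine-consistent)
claims, not that any particular real-world database is free of ambiguous
patterns. One such ambiguity survives even here: when disenrollment
truncates an R-CHOP cycle so that a lone trailing rituximab fill is all
that remains, the engine reads it as maintenance — indistinguishable, in
claims, from the truth; stochastic recovery is therefore asserted at
≥ 99%, with exact recovery only for zero-variance templates whose
same-day cycles cannot be split.

## Validation problem sizes

The test suite compares the engine against an independently coded
brute-force reference on an exhaustive enumeration of small event
configurations (about 28,000 cases of up to four drug events on date grids
straddling days 29/30/31 and 89/90/91, with and without SCT, CAR T and
apheresis placements); recovers ground truth exactly on 500 zero-variance
patients and at ≥ 99% on 2,000 stochastic patients; checks Kaplan–Meier
exactness against direct counting without censoring and 95% median-CI
coverage over 500 replicates of n = 200; recovers the generator's 58.1-
and 36.1-month medians and the analytic exponential 12-month failure
probability on a 7,522-patient survival-driven cohort; and audits every
written artifact for unmasked small cells. These sizes were chosen so the
enumeration is exhaustive at its grid and the stochastic checks have
narrow Monte-Carlo error while the whole suite stays comfortably
re-runnable on a laptop.

## Known limitations

* Fill dates proxy treatment start; inpatient administrations bundled
  under generic codes are invisible, as in any claims analysis.
* The maintenance definition is structural (list membership plus the
  solitary-exposure window), not clinical intent.
* The advancement clock on bridging-opened CAR T lines (from line start,
  not infusion) is one defensible literal reading; alternatives exist and
  would shift post-CAR T line boundaries.
* Eligibility monotonicity in enrollment holds for span extension; it is
  not claimed for arbitrary span edits.
* No covariate-adjusted or competing-risks models: the composite TTNT
  design treats death as an event, and only unadjusted product-limit
  estimates are produced.
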