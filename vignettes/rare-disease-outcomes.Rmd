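---
title: "Rare-disease burden and inpatient outcomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-disease burden and inpatient outcomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredx)
```

## The problem

Rare diseases — conditions below a population prevalence of roughly 1 in
2,000 — are individually uncommon but collectively frequent, and tertiary
referral hospitals concentrate them. `raredx` implements a reusable pipeline
for asking how rare-disease burden relates to inpatient outcomes in coded
administrative data: it identifies rare diseases among the ICD-10 codes of
hospital stays using a curated catalogue, groups patients by their number of
rare diseases (0, 1, more than one), and estimates adjusted associations with
in-hospital mortality, ICU admission, length of stay (LOS), ICU LOS and
30-day readmission.

## Catalogue matching: the wildcard rule

Catalogue entries are dot-free ICD-10 codes of three or more characters.
Matching is deliberately asymmetric:

* a **patient's code is truncated** until it equals a catalogue code — D57.1
  (sickle-cell anaemia without crisis) matches the catalogue entry D57
  (sickle-cell disorders);
* a **catalogue code is never truncated** — a patient coded A92 (other
  mosquito-borne viral fevers) is *not* matched by the catalogue entry A92.4
  (Rift Valley fever), because the unspecific patient code does not establish
  the rare diagnosis.

Equivalently, an entry matches exactly when it is a prefix of the patient
code. When several entries are prefixes of one code, the longest wins, so a
diagnosis maps to at most one entry even on a partially redundant catalogue.
Rare diseases per stay are counted as **distinct matched entries**: D57.1 and
D57.3 on the same stay are one rare disease, not two. Codes with no match
form the non-rare diagnosis count used as the disease-burden covariate.
A deliberate consequence: we count *distinct normalized codes*, so duplicated
billing rows cannot inflate the burden covariate.

Catalogue curation mirrors how such catalogues are assembled in practice:

* `merge_catalogues()` admits a candidate (code, description) pair only when
  the candidate's description agrees with the official reference description
  of that code (case- and whitespace-insensitive). This guards against
  mapping errors in nomenclature exports, the classic example being a rare
  diabetes form attached to E11.9, which officially denotes common type 2
  diabetes. Validation is driven by a user-supplied lookup table so runs are
  reproducible offline.
* `consolidate_codes()` replaces a complete set of child codes by their
  parent (Q05.0–Q05.9 become Q05), repeatedly until a fixed point. It also
  removes entries shadowed by a strict-prefix ancestor ({Q05, Q05.0} keeps
  only Q05): coverage is provably unchanged, and without this step a single
  disease could be counted as two catalogue entries. This is the package's
  resolution of the requirement that no consolidated entry be a prefix of
  another.
* `flag_high_prevalence()` reports entries whose observed prevalence reaches
  1/2,000 (inclusive). It never deletes anything: in the workflow this
  threshold triggers manual review, not automation.

## Cohort construction

Eligibility requires age ≥ 18 at admission and at least one coded diagnosis.
Age is evaluated at admission because eligibility should be fixed at entry.
Because patients with many stays — disproportionately the chronically ill —
would otherwise dominate, exactly **one stay per patient** is selected
uniformly at random, with a recorded seed (`select_one_stay_per_patient()`
restores the caller's RNG state, so the draw is reproducible and isolated).

Two covariates are derived from the **full stay history before selection**,
on the view that random selection decides which stay is analyzed, not which
events happened:

* `readmitted_30d`: any admission of the same patient within 30 days after
  the stay's discharge, boundary inclusive;
* `previous_stays_2y`: admissions in the 730 days before the stay's
  admission, categorized 0 / 1 / 2 / 3+.

Per-outcome cohorts follow the usual conventions: mortality and ICU
admission use everyone; LOS and readmission exclude stays that ended in
death (a death cannot be followed by discharge home or readmission); ICU LOS
additionally requires an ICU admission; readmission requires complete
readmission information. These rules nest, which the tests assert as an
invariant.

## Models

All effects are reported with Wald 95% intervals (z = 1.96). For a 2×2 table
the unadjusted odds ratio is the cross-product (a·d)/(b·c) with
CI = exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d)); zero cells raise an error
rather than receiving a silent continuity correction. Adjusted models are:

* **logistic regression** (mortality, ICU admission, 30-day readmission),
  reported as odds ratios;
* **log-linear regression** (LOS, ICU LOS): ordinary least squares on the
  natural logarithm of the outcome, reported as exponentiated coefficients —
  a factor of 1.28 reads as a 28% increase. Non-positive outcomes must be
  excluded upstream (the cohort rules guarantee this for LOS; ICU LOS is
  restricted to ICU stays, whose ICU time is positive).

Covariates and reference levels: exposure group (ref 0), age group (18–34 /
35–49 / 50–64 / 65–79 / 80+, ref 18–34), sex (ref F), discharge year
(continuous, centered at the first study year for numerical conditioning —
"per additional year" is unaffected), and the non-rare diagnosis count
(continuous, "per additional diagnosis"). Readmission models additionally
adjust for the previous-stay category (ref 0) and LOS in days. Sex-subgroup
models drop the sex covariate and keep everything else. Three sensitivity
analyses refit the mortality model: adding the patient's total stay count;
adding an exposure × non-rare-count interaction; adding the clinical-unit
group and its interaction with exposure.

Numerical choices: fits run through `stats::glm.fit`/`stats::lm.fit` on an
explicit model matrix with the IRLS tolerance fixed at 1e-8 (maxit 100), so
results are deterministic given the data. Rank-deficient designs,
non-convergence and runaway coefficients (|β| > 15, the signature of
quasi-complete separation) abort with named terms rather than returning
numbers. Degenerate factors (a single observed level) are rejected before
the fit. No multiple-testing adjustment is applied; each model reports its
own intervals.

The descriptive baseline table reports counts with percentages per exposure
group (percentages of an empty group are undefined, never 0), medians with
IQRs for skewed continuous variables, additionally mean (SD) for ICU days
(medians are 0 in most groups), chi-squared p-values for categorical rows
and Kruskal–Wallis for continuous rows.

## The synthetic population

`synthetic_config()` encodes the study conditions the pipeline is meant for;
its defaults describe a large tertiary-care adult inpatient population and
are the fixed reference conditions for all recovery checks:

* 165,908 patients, one third with multiple scheduled stays (geometric tail,
  mean 2.5 stays among them);
* 11.5% of patients carry at least one catalogued rare disease; 2053/19104
  of those carry more than one (count 2 + geometric);
* age-group and sex composition specified per exposure group (so exposure is
  confounded with demographics, as in real data, and adjustment matters);
* non-rare diagnosis counts negative-binomial (size 3) with means 4.7 / 5.8
  / 9.2, giving group medians 4 / 5 / 8;
* baseline (unexposed) outcome rates: mortality 2.2%, ICU admission 11.0%,
  readmission 4.8%; LOS log-normal with unexposed median 5 days (σ = 0.75);
  ICU LOS log-normal with unexposed median 2 days among ICU stays;
* true effects for every model term, defaulting to odds ratios 1.80 / 2.78
  (mortality), 1.64 / 2.23 (ICU), 1.57 / 1.64 (readmission) and factors
  1.28 / 1.49 (LOS), 1.14 / 1.40 (ICU LOS) for exposure groups 1 / >1, plus
  age, sex, diagnosis-count, year and previous-stay effects.

Outcomes are drawn **directly from the analysis models** — logistic for the
binary outcomes, log-normal for the stay lengths — with intercepts
calibrated by root-finding so the unexposed group attains the configured
baseline rates. That makes parameter recovery a well-posed test: the
estimator is asked for numbers the generator demonstrably put in.

Timelines are rolled out sequentially per patient (vectorized across
patients): a positive readmission draw schedules the next admission 1–30
days after discharge, a remaining scheduled stay starts at least 31 days
after discharge, and death ends the timeline. The 30-day flag in the output
table is then *re-derived from the dates* by the cohort module's own rule,
so the derivation logic is exercised on every dataset, not only in unit
tests. Half of all rare diagnoses are emitted as longer child codes of their
catalogue entry, so the truncation-matching path runs by default. ICU time
shares the LOS residual (correlation keeps ICU days below total stay length
almost surely; the residual cap at LOS affects < 1% of ICU stays and its
effect on group contrasts is well under 1%).

Two deliberate estimand consequences are worth knowing. Random selection of
one stay per patient (i) over-weights death stays slightly — a death ends
the timeline, so it competes with fewer sibling stays — and (ii) dilutes
readmission flags — a positive flag implies a further stay that competes in
selection. The analyzed marginal rates therefore differ mildly from the
per-stay baselines (about 3.4% vs 2.7% mortality, 3.7% vs 4.8% readmission
"Yes"), while group *contrasts* are nearly untouched: a 24-replicate pilot
at n = 80,000 put the readmission OR attenuation at about −0.8% on the log
scale, well inside the recovery tolerance.

What the generator does **not** emulate: realistic ICD-10 code frequencies,
seasonal or nonlinear calendar trends, hospital transfers, out-of-hospital
deaths, and any dependence of stay frequency on the exposure beyond the
readmission mechanism. Passing recovery tests therefore show that the
estimators are correct for data satisfying the stated models, not that the
models are correct for any particular hospital.

## Testing scale

The recovery study in the test suite runs 120 replicates at n = 150,000 and
checks, per configured effect, that the median estimate sits within ±5% of
the truth on the log scale and that the Wald intervals cover the truth at
≥ 93% pooled across effects and replicates. At this scale the Monte Carlo
error of the worst-placed median (readmission, group >1) is ≈ 0.005 on the
log scale against a 0.025 tolerance. Null calibration uses 40 replicates at
n = 12,000 with every effect set to 1 and identical group compositions; its
bounds were fixed in advance at roughly three times the Monte Carlo error of
each median. Selection uniformity is checked by a chi-squared
goodness-of-fit over 10,000 reseeded draws.

## Known limitations

* Wald intervals are used throughout, including near-boundary situations
  where profile likelihood would be preferable; separation aborts instead of
  switching to penalized fits.
* The catalogue shipped under `inst/extdata/` is a ten-entry toy for
  examples and tests, not a curated clinical catalogue; real analyses must
  supply their own.
* `previous_stays_2y` can only see stays inside the supplied table; histories
  truncated at the data boundary undercount, which real studies handle via
  the completeness flag.
* The 30-day readmission flag treats any subsequent admission as a
  readmission, with no cause linkage.
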