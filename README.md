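# raredx

Rare diseases — conditions rarer than about 1 in 2,000 — are individually
uncommon but collectively account for a substantial share of inpatients at
referral hospitals. `raredx` is an R package for epidemiologists and health
services researchers who want to quantify how rare-disease burden relates to
inpatient outcomes in routinely collected, ICD-10 coded hospital data. It
provides, as tested and reusable components:

* **Catalogue machinery** — a rare-disease catalogue data model with
  curation steps (description-validated merging of nomenclature candidates,
  parent-code consolidation, prevalence review flags) and the asymmetric
  *wildcard* matching rule: a patient's specific code (D57.1) is truncated to
  match a catalogue code (D57), but a catalogue code (A92.4) is never
  truncated to match an unspecific patient code (A92). The longest matching
  catalogue prefix wins.
* **Cohort construction** — adults with at least one diagnosis, one stay per
  patient selected uniformly at random with a recorded seed, stay-history
  covariates (30-day readmission flag, previous stays within two years)
  computed against the full history, and per-outcome sub-cohorts.
* **Exposure classification** — patients grouped by their number of distinct
  rare diseases: 0, 1, or >1.
* **Models** — unadjusted 2×2 odds ratios (OR = a·d/(b·c) with Wald 95% CI
  exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d))), multivariable logistic models
  (mortality, ICU admission, 30-day readmission) and log-linear models for
  the skewed stay lengths (OLS on ln y, effects reported back-transformed:
  Exp(B) = 1.28 reads as "+28%"), plus sex subgroups, sensitivity analyses
  and a Table-1-style descriptive baseline.
* **A synthetic inpatient generator** — draws multi-stay patient timelines
  and outcomes *from the analysis models themselves* with configurable true
  effect sizes, so every estimator is checked by parameter recovery.
* **An end-to-end pipeline** (`run_study()`, plus a small CLI) with a
  patient-flow report and a manifest recording every seed and row count.

## Worked example

Match codes against the packaged toy catalogue, reproduce an unadjusted odds
ratio from published-style group counts, and run a small synthetic study:

```r
library(raredx)

cat0 <- read_catalogue(system.file("extdata", "toy_catalogue.csv", package = "raredx"))
match_diagnosis(c("D571", "A92", "A9240", "Q05"), cat0)
#> [1] "D57"  NA     "A924" "Q05"
```

D57.1 truncates onto the catalogue entry D57; A92 is *not* matched by the
more specific catalogue entry A92.4; the exact code Q05 matches itself.

```r
# deaths among patients with one rare disease vs none:
# a = 1082 deaths / b = 15969 survivors, c = 3202 deaths / d = 143602 survivors
or_from_table(two_by_two(1082, 15969, 3202, 143602))
#>       term estimate ci_low ci_high      scale      n
#> 1 exposure     3.04   2.83    3.26 odds-ratio 163855
```

Patients with one rare disease had three-fold odds of in-hospital death
before adjustment.

```r
res <- run_study(synthetic_config(n_patients = 20000, seed = 42))
subset(res$results, model %in% c("mortality", "los") & grepl("^rare_group", term))
#>        model         term estimate ci_low ci_high          scale     n
#> 3  mortality  rare_group1     1.55   1.26    1.91     odds-ratio 20000
#> 4  mortality rare_group>1     2.82   1.89    4.22     odds-ratio 20000
#> 21       los  rare_group1     1.26   1.21    1.30 multiplicative 19323
#> 22       los rare_group>1     1.43   1.28    1.59 multiplicative 19323
```

The generator's default true effects are OR 1.80 / 2.78 for mortality and
factors 1.28 / 1.49 for length of stay in groups 1 / >1; at n = 20,000 the
adjusted estimates recover them within their intervals. `res$baseline` holds
the descriptive table, `res$flow` the patient-flow counts, and
`run_study(..., out_dir = "out")` writes all artifacts plus a manifest.

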