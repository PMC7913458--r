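Package: raredx
Title: Rare Disease Burden and Inpatient Outcomes from Coded Hospital Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies rare diseases in ICD-10 coded hospital stays by
    asymmetric prefix ("wildcard") matching against a curated catalogue,
    classifies patients by their number of rare diseases (0, 1, more than
    one), and estimates associations with in-hospital mortality, intensive
    care unit (ICU) admission, length of stay, ICU length of stay, and
    30-day readmission via logistic and log-linear regression with
    Wald-type confidence intervals. Ships catalogue curation utilities
    (description-validated merging, parent-code consolidation, prevalence
    review flags), reproducible one-stay-per-patient cohort construction,
    a synthetic inpatient data generator whose outcome models use
    configurable true effect sizes so that every estimator can be checked
    by parameter recovery, and an end-to-end pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
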