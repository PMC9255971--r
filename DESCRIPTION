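Package: polyrx
Title: Polypharmacy, Inappropriate-Medication and Drug-Interaction Analysis
    for Geriatric Oncology Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying medication risk in cohorts of older adults
    with cancer: ingestion and normalization of per-patient medication logs,
    polypharmacy classification, WHO ATC classification with level rollups,
    a declarative rules engine for potentially inappropriate medications
    (Beers-2019-style and STOPP-style criteria), severity-graded detection of
    drug-drug and drug-cancer-treatment interactions, interaction-network
    construction with graph metrics (density, diameter, triadic closure) at
    nested ATC levels, chord-matrix export, and bivariate association
    statistics (prevalence odds ratios with Woolf confidence intervals,
    Fisher exact, chi-square, t-test, univariate logistic odds per additional
    medication). Includes a seeded synthetic-cohort generator with a
    planted-truth ledger for recovery testing, and an end-to-end pipeline
    runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
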