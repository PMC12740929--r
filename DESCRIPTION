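Package: faersignal
Title: Pharmacovigilance Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    spontaneous adverse-event report databases in the FAERS quarterly-file
    layout (DEMO/DRUG/REAC/THER). Reads the "$"-delimited ASCII dialect and a
    simple CSV dialect, deduplicates case versions by FDA receipt date and
    report version, normalizes drug names through a synonym table, selects
    primary-suspect reports, builds per-term 2x2 contingency tables at the
    MedDRA Preferred Term and System Organ Class levels, and computes four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with chi-square, Bayesian confidence propagation neural
    network information component, and the unshrunk empirical Bayes geometric
    mean) with their lower confidence bounds and a conjunction signal
    criterion. Also provides time-to-onset summaries with Weibull
    shape/scale modelling and hazard-pattern classification, descriptive
    report-characteristics tables, and a seeded synthetic-data generator with
    a ground-truth answer key for validating signal recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
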