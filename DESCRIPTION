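Package: tcevigil
Title: Multi-Level Pharmacovigilance Signal Detection for T-Cell Redirecting Therapies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spontaneous-reporting-system (SRS) pharmacovigilance of
    T-cell engager (TCE) and CAR-T therapies: ingestion and deduplication of
    FAERS-dialect quarterly ASCII files, eight-algorithm disproportionality
    analysis (ROR, PRR, chi-square, Fisher, observed/expected, BCPNN by normal
    approximation and MCMC, and the DuMouchel gamma-Poisson EBGM) with
    threshold flags and a drug-specificity ratio, time-to-onset summaries with
    interval-censored Weibull shape-parameter analysis, lift-weighted adverse
    event co-occurrence networks with Louvain communities and eigenvector
    hubs, cohort comparison and univariate risk-factor statistics, and a
    seeded synthetic SRS generator with planted signals for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
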