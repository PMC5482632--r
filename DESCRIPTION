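Package: rankscreen
Title: Rank-Based Cross-Platform Expression Screening and Relapse Outcome
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential-expression screening of microarray cohorts using
    per-sample percentile rank scores, average rank scores (ARS) and delta
    statistics, which are invariant to monotone platform distortions and so
    comparable across array platforms. Includes rank-based expression (RBE)
    curves, probe-to-gene collapsing, a configurable gene-plasticity score,
    and the downstream biomarker evaluation toolkit used in leukemia relapse
    studies: ROC curves with DeLong confidence intervals and Youden-index
    cutoffs, median dichotomization, Kaplan-Meier relapse-free survival,
    cumulative incidence of relapse under competing risks, Gray's test, Cox
    proportional-hazards models with sequential backward elimination, and
    qPCR relative quantification (2^-ddCt and standard-curve efficiency).
    Ships seeded synthetic-data generators for expression cohorts with
    spiked rank-shifted genes and for clinical cohorts with competing-risks
    event structure, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cmprsk,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
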