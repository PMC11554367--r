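Package: insulinRI
Title: Indirect Reference Intervals for Fasting Insulin and HOMA-IR from
    Laboratory Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates reference intervals for fasting insulin and the
    HOMA-IR insulin-resistance index indirectly, from mixed routine
    laboratory data rather than recruited healthy volunteers. Provides a
    configurable exclusion-criteria filter engine with per-criterion audit,
    HOMA-IR and unit-conversion arithmetic under both the WHO and the
    legacy reciprocal insulin conventions, and a statistical pipeline that
    removes outliers with medcouple-adjusted boxplot fences, symmetrizes
    the data by a skewness-gated Box-Cox transform, deconvolves the healthy
    subpopulation by Gaussian-mixture EM with BIC model selection, truncates
    at posterior-responsibility boundaries (with antimode overrides), and
    estimates the central 95% by responsibility-weighted nonparametric
    percentiles with percentile-bootstrap 90% confidence intervals. A
    synthetic-cohort generator with known healthy quantiles, a Harris-Boyd
    sex-partitioning check, and an end-to-end study report round out the
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
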