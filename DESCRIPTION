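Package: atrophytrials
Title: Reliability, Mixed Models and Trial Power for Longitudinal Brain
    Atrophy Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for serial brain-volume measurement
    techniques. Simulates longitudinal volume and pairwise direct-change
    datasets with the variance structure of a multi-visit, repeat-scan
    study design; computes short-interval repeatability, symmetry and
    transitivity statistics; fits two restricted maximum likelihood (REML)
    linear mixed models -- a random-slope model with fixed subject effects
    and random visit/scan effects for repeated volumes, and a signed
    visit/scan effect model for repeated direct measures of change; and
    converts fitted group models into effect sizes and required clinical
    trial sample sizes with bias-corrected and accelerated (BCa) bootstrap
    confidence intervals and paired head-to-head comparisons between
    techniques.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    yaml
Config/testthat/edition: 3
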