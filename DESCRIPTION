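Package: binmr
Title: Mendelian Randomization Estimators for Binary Exposure and Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Causal-effect estimation in Mendelian randomization when the
    instrument, exposure and outcome are all binary. Implements three
    Wald-ratio estimators (logistic regression, linear probability model,
    and a prevalence-based transformation between the log-odds and linear
    scales) alongside three instrumental-variable estimators (structural
    equation modelling, two-stage predictor substitution and two-stage
    residual inclusion), a confounded bivariate-Bernoulli simulator with
    scenario and sensitivity grids, a replicated Monte-Carlo bias study
    summarised as median and quartile tables, and an applied workflow for
    cohort data with a SNP-exposure association screen and
    confounder-adjusted estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
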