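Package: sleeple
Title: Sleep Profiles and Cardiovascular-Disease-Free Life Expectancy
Version: 0.1.0
Authors@R:
    person("Sleeple", "Maintainers", email = "maintainers@sleeple.org",
           role = c("aut", "cre"))
Description: Estimates cardiovascular-disease-free life expectancy and years
    of life lost across sleep profiles with a continuous-time three-state
    (healthy, CVD, dead) Cox Markov model on the age timescale. Provides
    composite sleep scoring from questionnaire responses, code-list
    phenotyping of clinical sleep disorders from linked electronic health
    records (ICD, Read v2, CTV3, BNF vocabularies) with a pre-enrollment
    lookback, an exclusion cascade and counting-process data builder with a
    restriction age of 81, a left-truncated Cox fitter with Efron ties and
    Breslow baselines, Aalen-Johansen state-occupation curves integrated
    into restricted state-specific life expectancies with nonparametric
    bootstrap confidence intervals, Fine-Gray subdistribution hazard ratios
    for comparability, and a synthetic-cohort generator with known Gompertz
    transition intensities that serves as a ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
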