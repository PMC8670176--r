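Package: perijoint
Title: Joint Random-Effects Models for Preterm Birth and Perinatal Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of preterm birth and perinatal death in
    mother-clustered birth-registry data. Fits shared-parameter and
    separate-but-correlated random-intercept bivariate logistic models, and
    random-effects multinomial models for the four-category co-occurrence
    outcome, by maximum likelihood with adaptive Gauss-Hermite quadrature.
    Provides cluster-robust sandwich variances, BIC model comparison,
    odds-ratio reporting, stratified proportion tables with chi-square tests,
    ordinary least-squares annual trend analysis, and a reproducible
    mother-clustered synthetic registry generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    lme4,
    tidyr,
    nnet,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
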