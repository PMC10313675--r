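Package: equigen
Title: Pedigree-Based Quantitative Genetics of Racehorse Speed
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An analysis pipeline for estimating quantitative genetic
    parameters of racehorse speed from pedigree and race-performance data.
    Fits univariate and bivariate animal models by restricted maximum
    likelihood (REML) and by Gibbs-sampling MCMC, partitioning phenotypic
    variance into additive genetic, permanent environment, trainer and
    residual components; estimates cohort trends in predicted breeding
    values; tests whether genetic trends exceed neutral expectation by
    gene-dropping simulation down the observed pedigree; estimates genetic
    correlations of speed across race-distance categories; and converts
    genetic trends into realised selection intensities under truncation
    selection.  A synthetic-data generator emulates the pedigree and
    race-record structure of the thoroughbred population with known ground
    truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    Matrix,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
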