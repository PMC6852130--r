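Package: vegbench
Title: Best-on-Offer Vegetation Benchmarks from Floristic Plot Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates best-on-offer biodiversity benchmarks - posterior
    quantiles of native species richness and summed percent cover for six
    plant growth forms - from floristic plot surveys. Fits multivariate
    hierarchical Bayesian models (Poisson for richness, lognormal for cover)
    with survey-level multivariate-normal overdispersion under an LKJ
    correlation prior, vegetation classes nested in formations,
    bioregion-specific rainfall effects, and seasonal month effects modelled
    either as regionally varying first-order random walks (dynamic) or as
    exchangeable month intercepts (static). Includes tools to aggregate
    species records to growth-form vectors, accumulate and impute 12-month
    rainfall levels, derive benchmark tables over bioregion-by-class grids,
    compare them with expert-elicited values, and simulate data from the
    full generative model. Posterior sampling uses a built-in No-U-Turn
    sampler with compiled gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    lubridate,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
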