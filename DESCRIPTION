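Package: stmort
Title: Bayesian Spatio-Temporal Small-Area Mortality Modelling and Life
    Expectancy Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hierarchical Bayesian modelling of small-area mortality counts
    by age group, area, calendar year and deprivation decile. Fits a Poisson
    model whose log rate decomposes into smooth age, time and deprivation
    effects (first-order random-walk priors), a spatially structured area
    effect (intrinsic conditional autoregressive prior) and unstructured
    interactions, by adaptive Metropolis-within-Gibbs MCMC. Posterior samples
    of age-specific rates are converted to life expectancy at birth through a
    Chiang-style abridged life table, and area-years with unexplained excess
    mortality are flagged by posterior exceedance probabilities on the
    space-time interaction. Includes a synthetic-data generator that draws
    every model component from its prior so that inference and detection can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
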