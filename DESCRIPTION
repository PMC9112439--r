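Package: scanmap
Title: Space-Time Scan Statistics and Bayesian Disease Mapping for
    Small-Area Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small-area spatio-temporal analysis of cancer
    registry data aggregated to (tract, year, age-group) counts: direct
    age standardization against a standard million population, internally
    standardized expected counts and standardized incidence ratios, a
    Bayesian log-linear Poisson relative-risk model with intrinsic
    conditional autoregressive (ICAR) spatial effects, linear time trend
    and optional space-time interaction fitted by Markov chain Monte
    Carlo, a cylindrical space-time scan statistic with Poisson
    log-likelihood-ratio scoring and Monte Carlo significance, rank-sum
    comparison of covariates between cluster and non-cluster tracts, and
    a fully reproducible synthetic registry generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    Matrix
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
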