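Package: epiquake
Title: Integrated Earthquake Casualty Estimation with Human Vulnerability Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments HAZUS damage-state casualty rates with four
    human-related risk factors (age over 65, female gender, physical
    disability, low socioeconomic status) through logistic equations whose
    coefficients come from a random-effects meta-analysis of published odds
    ratios. Provides DerSimonian-Laird pooling of study effects, conversion
    of casualty rates to logistic intercepts, synthetic population
    generation from census-tract marginals, a hierarchical
    fatal-severe-moderate-light severity cascade, and city-level
    aggregation with comparison against the unadjusted HAZUS rates.
    Ships the census-tract profiles, study effects and casualty-rate
    tables needed to run an all-collapse scenario for the city of
    Tiberias, Israel.
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
    jsonlite,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
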