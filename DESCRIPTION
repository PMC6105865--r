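Package: appdensity
Title: Grid Sampling and Ecological Poisson Models of Geosocial App User Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the spatial density of geosocial networking
    app users over a systematic sampling grid and modelling that density
    against areal population-weighted neighbourhood covariates. Includes a
    synthetic-geography generator (Voronoi dissemination areas with spatially
    autocorrelated census-style covariates and an inhomogeneous Poisson user
    point process), the virtual sampling protocol (distance-ordered profile
    listings with a positional rule for location-withheld profiles, buffer
    counting with deduplication, land-area denominators), combined area and
    population weighted covariate aggregation, Poisson regression with a
    forced sampling-time block, backward AIC model selection, likelihood
    ratio tests, McFadden pseudo r-squared, incidence rate ratio reporting,
    and Bonferroni outlier detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
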