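Package: descurves
Title: Taxonomic Description Curves: Growth-Curve Fitting, Rate Anomalies
    and Bayesian Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cumulative species-description curves of
    taxonomic groups (1753 onwards). Fits a left-sided half-normal cumulative
    model (and Gompertz / von Bertalanffy alternatives) to yearly description
    counts by MCMC, derives per-group curve parameters (initial description
    time, future descriptions ratio, curve residuals), flags description-rate
    anomalies with a five-year moving-window rule, and fits a Bayesian path
    (structural equation) model linking biological and societal predictors to
    the curve parameters, with a posterior predictive p-value for model fit.
    Includes a synthetic-data generator with known ground truth for end-to-end
    validation, tidyverse-style tabular interfaces, broom-style tidy() and
    glance() methods, and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    rjags,
    coda,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
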