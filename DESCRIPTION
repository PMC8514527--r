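Package: climmort
Title: Country-Level Temperature-Related Mortality Damage Functions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits country-level damage functions linking projected warming to
    percent changes in heat- and cold-related mortality, using no-intercept
    regressions with country-clustered (CR1) covariance and leave-one-out
    cross-validation for model selection.  Projects the fitted damage
    functions to all countries under scenario warming fields, with and
    without income-based adaptation of heat sensitivity, and aggregates to
    global mortality-rate changes, delta-method confidence intervals and
    excess-death counts.  Includes a synthetic-data generator (toy worlds,
    gridded climatologies, clustered-noise response tables, income growth
    paths) so the full pipeline runs and is testable without external data,
    plus population-weighted climatology utilities, CSV readers/writers and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
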