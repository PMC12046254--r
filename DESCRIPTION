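Package: trendmediate
Title: Causal Mediation Analysis of Excess Search Volumes with Seasonal
    ARIMA Counterfactuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for infodemiology panel studies that ask how much of an
    epidemic shock's effect on population mental-health indicators is
    carried by behavioural responses.  Weekly relative search volumes are
    compared against a counterfactual baseline forecast from a seasonal
    ARIMA model selected by a stepwise AICc search, yielding weekly excess
    search volume.  Excess outcomes, daily mortality exposures and
    residential-mobility mediators are aggregated to a country-by-month
    panel, and a three-model two-way fixed-effects causal mediation
    analysis decomposes the total effect of deaths on excess searches into
    a mobility-mediated and an alternative component, with delta-method
    standard errors for both effects and for the proportion mediated.
    Includes a synthetic-data generator with known ground truth for
    validation, tidy accessors, and ggplot2 visualisations.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
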