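Package: donorcast
Title: Hierarchical Time Series Forecasting of Blood Donations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coherent forecasting of blood-bank donation counts
    organised in a gender-by-ABO-blood-group hierarchy. Builds the summing
    matrix of a strict balanced tree, fits independent ARIMA (automatic
    stepwise AICc order selection) and Holt-Winters base forecasts per node,
    reconciles them by bottom-up, top-down (average historical proportions,
    proportions of historical averages, forecast proportions) and
    least-squares optimal-combination methods, and evaluates methods by
    out-of-sample MAPE. Includes a synthetic monthly donation-series
    generator with seasonal structure and a pandemic-style level-shift
    injector, so the full pipeline is testable without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
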