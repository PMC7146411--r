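Package: cropet
Title: Forecasting Crop Evapotranspiration from Remote Canopy Parameters
    and Air Temperature Forecasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for short-range (1-5 day) forecasting of crop
    evapotranspiration (ETc) for irrigation scheduling. Computes a
    remote-sensing-based crop coefficient by inserting multispectral-derived
    leaf area index (CLAIR inversion of the weighted difference vegetation
    index) and broadband albedo directly into the Penman-Monteith equation
    (one-step approach), calibrates the Hargreaves-Samani equation locally
    against Penman-Monteith reference evapotranspiration, reduces ensemble
    numerical weather prediction output to daily site values with mean-bias
    correction of temperature, and verifies accumulated forecasts with
    BIAS/RMSE skill scores. Includes a synthetic generator of station
    weather, ensemble forecasts and maize canopy seasons for end-to-end
    experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
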