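Package: copolsim
Title: Simulation of Copollutant Exposure Measurement Error in Poisson
    Time-Series Health Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the impact of correlated exposure measurement
    error on relative-risk estimates from two-pollutant (copollutant) Poisson
    time-series models of daily health counts. Generates synthetic
    multi-pollutant exposure panels in which spatially refined exposure
    metrics are linked to central-site measurements by ZIP-specific linear
    calibrations with additive and multiplicative bias and correlated
    residuals; estimates those calibrations back from data; simulates "true"
    (error-free) exposures and Poisson emergency-department counts; fits the
    health model with true and with error-prone exposures; and summarises the
    Monte Carlo results as mean relative risks, percent attenuation, RMSE
    ratios, power / type I error, and confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    MASS,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
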