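Package: fusiondesign
Title: Fusion-Design and BACI Estimators of Bird Flight Diverter Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the effectiveness of bird flight diverters (power-line
    markers) from carcass-search and bird-flight-survey data. Implements the
    fusion design, in which corrected carcass counts are offset by concurrently
    observed flight intensity, alongside the classical before-after (BA) and
    before-after control-impact (BACI) estimators and a synchronicity test for
    the BACI assumption of equal relative flight-intensity changes across
    sites. Includes a Monte Carlo simulator of paired flight and carcass
    datasets (overdispersed negative binomial flights, per-bird binomial
    collisions) and evaluation tools that quantify each estimator's relative
    bias, statistical power and false-positive rate.
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
    MASS,
    stats,
    splines,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
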