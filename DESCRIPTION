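Package: esvca
Title: Land-Use Change Simulation and Ecosystem-Service Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing land-use/land-cover change (LUCC) and its
    consequences for ecosystem-service value (ESV). Implements the CA-Markov
    approach to land-change simulation (transition-probability estimation,
    Markov area projection, cellular-automaton spatial allocation under
    neighbourhood suitability), Kappa map-agreement validation,
    equivalent-factor (benefit-transfer) ESV accounting by land-cover class,
    service function and zone, change-rate and contribution reporting, and
    coefficient-sensitivity (elasticity) analysis. Ships a synthetic-landscape
    generator with known ground truth and the coefficient and area tables of
    the Northern Tianshan Mountain Economic Zone case study.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
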