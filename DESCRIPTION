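Package: infrachoice
Title: Infrasound and Wind Covariates in Albatross Movement Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether wide-ranging seabirds orient toward
    regions of high microbarom infrasound when they commence sustained flight.
    Segments GPS tracks into travel, search and rest states with a three-state
    hidden Markov model on step length and turning angle; extracts decision
    points at the start of qualifying flight bouts; tiles the surrounding
    ocean into great-circle sectors; integrates a modelled microbarom
    sound-pressure field and wind covariates over each sector; and fits
    matched conditional-logit (1-of-6) habitat-selection models with
    cluster-robust variance, QIC model comparison, likelihood-ratio tests and
    concordance. Includes a synthetic-data generator with known selection
    coefficients so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    survival
Config/testthat/edition: 3
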