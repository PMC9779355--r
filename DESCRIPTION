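Package: ecocorridor
Title: Habitat Suitability and Ecological Corridors from Coupled
    Maximum-Entropy and Minimum-Cumulative-Resistance Models
Version: 0.1.0
Authors@R: person("ecocorridor", "authors", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A raster pipeline for presence-background species distribution
    modelling and landscape connectivity in alpine systems. Fits a
    maximum-entropy (MaxEnt-style) model by L1-regularized coordinate
    descent, classifies continuous suitability into four IPCC-style classes,
    derives a contribution-weighted resistance surface from the fitted
    response curves, and extracts least-cost ecological corridors between
    source patches on the minimum cumulative resistance surface. Also
    provides CA-Markov land-use projection, FRAGSTATS-style landscape
    pattern metrics (NP, PD, LSI, CONTAG, DIVISION, SHEI), occurrence-record
    spatial thinning, and a synthetic-landscape generator with known
    response structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
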