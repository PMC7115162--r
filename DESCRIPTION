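Package: wcmbiomass
Title: Corn Biomass and Soil Moisture Retrieval from Dual-Polarized SAR
    with an Optical Transfer Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates the semi-empirical Water Cloud Model on dual-polarized
    (HH/HV) C-band radar backscatter from point observations of corn fields,
    inverts the two calibrated equations simultaneously for above-ground
    biomass and volumetric soil moisture with a Levenberg-Marquardt solver,
    fits four vegetation-index biomass regressions (NDVI, RTVI, SR, SRre),
    and trains a small feed-forward neural network that transfers radar-based
    biomass estimates onto the optical-estimate scale so biomass can be
    monitored regardless of satellite source. Ships the 66-point ground and
    satellite observation table used to develop the method, plus a synthetic
    observation generator for parameter-recovery testing.
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
    utils,
    withr,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
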