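Package: chiawater
Title: Satellite-Style Crop Water-Use Comparison and Replacement Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparing the growing-season water use of crops from
    satellite-like evapotranspiration (ET), canopy-cover and water-use-efficiency
    (WUE) products, with chia (Salvia hispanica) as the reference replacement
    crop. Provides a synthetic scene generator with known ground-truth flux
    curves, pixel-center zonal statistics over field polygons, derivation of
    NDVI, WUE (GPP/ET) and canopy-partitioned transpiration, monthly-mean and
    growing-season aggregation, crop-to-chia ratio summaries with standard
    errors and temperature regressions, and projection of regional water
    savings and per-hectare economic scenarios for crop replacement.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
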