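Package: fusionyield
Title: Spatiotemporal Image Fusion, Mixed-Pixel Diagnostics and NDVI-Based
    Crop Yield Estimation
Version: 0.1.0
Authors@R:
    person("fusionyield", "developers", email = "fusionyield@example.org",
           role = c("aut", "cre"))
Description: Field-scale crop monitoring toolkit combining the flexible
    spatiotemporal data fusion algorithm (FSDAF) for predicting
    fine-resolution NDVI imagery from one fine reference image and a coarse
    time series, a Mixed Degree Index (MDI) quantifying how strongly a
    plot's coarse pixels blend surrounding land cover, phenology-driven
    selection of reference dates from NDVI time series, and linear
    NDVI-to-yield regression with yield-monitor preprocessing. Ships a
    synthetic scene generator with known ground truth so every stage can be
    validated end to end. Rasters are read and written as plain-text ESRI
    ASCII grids and plot boundaries as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
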