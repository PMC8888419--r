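Package: phylrisk
Title: Grape Phylloxera Risk Mapping from Soil Sand Content and Soil
    Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable raster pipeline for mapping the environmental risk
    of grape phylloxera (Daktulosphaira vitifoliae) establishment from two
    drivers: soil sand content and summer soil temperature. Provides a
    lightweight georeferenced grid model with ESRI ASCII and single-band
    GeoTIFF input/output, depth-weighted aggregation of layered soil-sand
    rasters with gap filling, quality-controlled summarization of 15-minute
    station soil-temperature records to seasonal mean daily maxima,
    ordinary kriging interpolation with empirical variogram estimation and
    weighted-least-squares model fitting, threshold-based risk
    classification with a five-class combination matrix, area summaries,
    and validation of point sites against the risk map. A synthetic-data
    generator produces spatially autocorrelated soil fields, multi-year
    diurnal station series, and validation sites with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
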