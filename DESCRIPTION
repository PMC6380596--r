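Package: cropalloc
Title: Spatial Downscaling of Crop Statistics with Robustness Scenarios
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downscales administrative-level crop production statistics
    (harvested area, production, yield) to a pixel grid using either a
    simple cropland-proportional allocation or a cross-entropy allocation
    primed by informed priors built from land suitability, potential
    yields, prices and market access. Provides a synthetic-landscape
    generator with nested administrative units and a known ground-truth
    allocation, a suite of methodological robustness scenarios (allocation
    method, crop aggregation, passive remainder allocation, suitability,
    market-access and price toggles, coarsened reporting levels), Gaussian
    focal-weight pre-smoothing, a bounded spatial similarity index with
    crop-level and area-weighted country-level aggregation, presence and
    absence shares, and Moran's I spatial autocorrelation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
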