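Package: lmdi
Title: Land Multi-Degradation Index Modelling for Agricultural Landscapes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the co-occurrence of land degradation processes on
    agricultural land. Twelve degradation-process rasters (water and wind
    erosion, soil organic carbon loss, salinization, acidification,
    compaction, nutrient imbalance, pesticide and heavy-metal pollution,
    vegetation degradation, groundwater decline, aridity) are binarized into
    Critical/Non-critical layers by a documented threshold registry, summed
    pixel-wise into a Land Multi-degradation Index (LMI), binned into
    degradation classes and reported per zone and land-use stratum. Includes
    pixel-wise Mann-Kendall and Sen's slope trend detection, dominant
    process-combination analysis, threshold-perturbation Monte-Carlo
    uncertainty with a Random-Forest class-probability model, a
    synthetic-scenario generator with known ground truth, lightweight GeoTIFF
    input/output, and an end-to-end pipeline command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
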