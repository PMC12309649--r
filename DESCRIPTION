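Package: kbagap
Title: Gap Analysis of Key Biodiversity Area Coverage of Species' Area of Habitat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for auditing how well a network of conservation sites (such
    as Key Biodiversity Areas) represents species' Area of Habitat (AOH) maps.
    Computes species-map by site overlap matrices on an equal-area grid,
    classifies under-represented species with nested percentage thresholds,
    tests taxonomic, habitat and Red List biases with resampling null models
    and exact binomial tail probabilities, and summarises gaps on coarse
    equal-area grids. Includes a synthetic-data generator (landscapes, binary
    habitat rasters, partially overlapping and occasionally invalid site
    polygons, species attribute tables) so the whole pipeline is testable
    without proprietary global datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
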