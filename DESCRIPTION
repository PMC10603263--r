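Package: spindlegraph
Title: Quantitative Analysis of Microtubule Spatial Graphs from
    3D-Reconstructed Mitotic Spindles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reads and writes AmiraMesh ASCII HxSpatialGraph files of
    segmented microtubules, standardizes them (uniform resampling,
    spindle-axis reorientation, plus/minus-end assignment, kinetochore
    microtubule and k-fiber classification), and computes geometric
    statistics of spindle organization: microtubule length and
    tortuosity, k-fiber twist and helicity, alpha-shape cross-section
    area and packing density, outer-kinetochore distance, KMT-number
    statistics, minus-end branching, and global microtubule-microtubule
    interactions.  Includes a ground-truth synthetic spindle generator
    and a batch pipeline writing CSV analysis tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
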