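Package: tilestitch
Title: Stage-Model-Constrained Stitching of Microscopy Tile Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stitches rectangular grids of partially overlapping microscopy
    image tiles into a single mosaic. Pairwise tile translations are computed
    by the Phase Correlation Method with multi-peak disambiguation scored by
    normalized cross-correlation; a mechanical stage model (overlap, camera
    angle, stage repeatability, actuator backlash tolerance) is estimated from
    the translation tables and used to repair and refine translations by
    constrained hill climbing within a (4r)^2 window; tiles are placed along a
    weighted maximum spanning tree and blended into the mosaic. Includes a
    synthetic acquisition generator with known ground truth and
    reference-based accuracy metrics (Hungarian ROI matching, Kabsch frame
    alignment, centroid distance and area errors, blank-pixel counting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools
Suggests:
    igraph,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
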