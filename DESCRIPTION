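Package: raftsense
Title: Label-Free Sensing and Image-Guided Splitting of Cell Colonies on
    Quad Microraft Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free bright-field cytometry of adherent cell
    colonies cultured on quad microraft arrays. Implements
    background-subtracted standard-deviation z-projection (B-SDP) contrast
    enhancement and a calibrated morphological/texture filter chain for
    colony segmentation; microraft grid detection, row/column indexing,
    interpolation of missing sites, and tracking across timepoints;
    per-colony, per-raft coverage cytometry with growth classification and
    segmentation-quality metrics; and an image-guided microraft release
    planner with nearest-neighbour routing and a closed-loop dislodgement
    controller. A synthetic scene generator renders bright-field z-stacks
    of microraft arrays with exact ground truth so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
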