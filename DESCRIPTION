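Package: shapepath
Title: Cell-Body Shape Profiling and Directional-Stability Statistics for
    Migrating Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of cell-body shape and directional-movement
    stability in time-lapse imaging of migrating neurons. Segments the cell
    body of a GFP-traced cell from phase-contrast frames (sobel edge
    detection, morphological closing, moment-equivalent ellipse fit with
    eccentricity and solidity quality control), links nuclear detections
    into single-cell trajectories with five-point positional smoothing,
    fits a robust bisquare projected path to the first half of each track,
    and computes three angular coordination statistics (axis rotation,
    turning angle, movement-vs-axis accordance), a bivariate angular kernel
    density with peak-density read-out, and seed-based resampling tests for
    peak density and accordance rate. Ships a calibrated synthetic-data
    generator (tracks and rendered phase/nuclear frame pairs with ground
    truth) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
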