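Package: dpetrack
Title: Dynamic Contour Evolution Segmentation and Graph-Based Cell Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for contour-based instance segmentation and
    multi-object tracking of cells in grayscale time-lapse microscopy. Provides
    a Fourier-series Kolmogorov-Arnold (FT-KAN) convolutional feature extractor,
    chain-code boundary feature enhancement, an iterative Dynamic Profile
    Evolution (DPE) contour refiner driven by image landmarks, and a
    multi-feature similarity-boosted bipartite graph tracker with occlusion
    handling. Includes a synthetic time-lapse generator with full ground truth,
    COCO-style detection metrics, CLEAR-MOT tracking metrics, per-cell
    morphometry (perimeter, area, circularity, aspect ratio), trajectory
    analytics with origin normalization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
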