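Package: vlsmlm
Title: Virtual Light-Sheet Filtering for Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Axial optical sectioning of 2D single-molecule localization
    microscopy (SMLM) data by post-processing. A bead z-stack is used to
    calibrate thresholds on the fitted point-spread-function width and
    amplitude so that only emitters within a thin "virtual light-sheet"
    around the focal plane are retained, with known confidence and recall.
    Includes a camera-level synthetic microscope (bead z-scans and blinking
    SMLM movies with ground truth), spot detection and five-parameter 2D
    Gaussian fitting, precision-recall threshold selection for a structural
    and a confidence imaging mode, localization-table filtering and cluster
    classification, and Gaussian super-resolution rendering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
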