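Package: bmareader
Title: Spot Calling, Calibration and Panel Statistics for Fluorescence
    Biomarker Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for slide-format fluorescence biomarker
    microarrays imaged one well at a time by an RGB camera.  Implements the
    onboard image-analysis chain of a point-of-care microarray reader:
    red-channel extraction, Gaussian smoothing, intensity thresholding,
    contour labelling with area and circularity filters, centroid-based
    spot localization anchored on printed control spots, annulus
    background-subtracted spot quantification, row-wise intensity
    profiling, four-parameter logistic standard-curve calibration, and
    panel-level statistics (Welch tests, ROC/AUC with DeLong confidence
    intervals, cross-platform correlation, GenePix results import).  A
    ground-truth-emitting synthetic slide renderer supports end-to-end
    validation without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    jsonlite,
    clue,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
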