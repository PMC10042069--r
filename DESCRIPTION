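Package: detcal
Title: Confidence Calibration and Evaluation for Object Detection in
    Coronary OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for assessing and calibrating the confidence of object
    detections, developed around calcified-plaque detection in intravascular
    optical coherence tomography (OCT). Matches predicted boxes to
    ground-truth annotations by intersection-over-union, computes precision,
    recall, F1 and the expected calibration error (ECE), and fits a dependent
    logistic calibration map -- a two-population multivariate Gaussian
    log-likelihood-ratio model over confidence and box-center features -- to
    recalibrate detection scores. Includes a synthetic detection-stream
    simulator with a known true calibration function, so every stage is
    testable without imaging data or a trained detector, plus the two
    augmentation operators appropriate to OCT imagery: motion blur and
    horizontal flip with bounding-box remapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
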