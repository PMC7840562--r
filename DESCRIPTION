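Package: platescale
Title: Marker-Free Dining Plate Size Estimation from Egocentric Image
    Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the radius of a circular dining plate from a
    sequence of ellipse observations captured by a chest-worn wearable
    camera, removing the need for a fiducial marker in image-based
    dietary assessment.  Provides exact circle-pose recovery from a
    single image ellipse via cone-plane intersection, a simplified linear
    model relating the reciprocal semimajor axis to camera-to-plate
    distance, one-time calibration of the plausible distance range from a
    plate of known radius, pooled-distance scoring with Gaussian peak
    fitting to estimate unknown plate radii, direct least-squares ellipse
    fitting from boundary points, a ground-truthed synthetic
    eating-episode simulator, and cross-estimation error metrics with a
    command-line interface.
License: MIT + file LICENSE
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
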