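Package: monogaze
Title: Monocular Gaze Estimation with Calibration Correction and
    Uncertainty Visualization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete monocular eye-tracking gaze-estimation pipeline for
    head-mounted trackers: dark-pupil detection with a distance-transform
    uncertainty field, concentric-ring calibration-marker detection in the
    world camera, fitting of a bivariate second-order polynomial gaze mapping
    by singular value decomposition, correction of raw gaze estimates by
    Inverse Distance Weighting (IDW) and by a time-windowed Modified IDW,
    quantitative evaluation in centimetres and degrees of visual angle, and
    qualitative gaze-uncertainty maps (Gaussian and pupil-shaped kernels,
    bump-mapped relief, IDW-interpolated error maps).  A synthetic-session
    generator with known ground truth supports end-to-end testing without
    recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
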