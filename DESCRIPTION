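Package: ankleproj
Title: Projection-Line Ankle Angle Measurement from RGB-D Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the sagittal-plane ankle angle from integrated RGB and
    depth (time-of-flight) camera recordings using the projection-line method:
    a body mask detected in the RGB image is registered onto the depth image,
    cleaned by a depth window, and a scan column across the lower leg yields a
    foot-to-shank depth profile whose kink, located after Savitzky-Golay
    smoothing and chord rotation, is the ankle; two segment-wise regressions
    give the joint angle. Also provides the keypoint (knee-ankle-foot)
    comparator angle, dual-IMU Euler-pitch gold-standard angles with
    recording-clock correction, method-agreement statistics (Pearson and
    Spearman with Fisher-Z intervals, RMSE, MAE), depth-error propagation to
    the angle, and a synthetic articulated-leg depth-scene generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
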