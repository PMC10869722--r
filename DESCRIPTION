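Package: prosgait
Title: Validating Video-Derived Gait Measures Against a Shank-Worn IMU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating spatiotemporal gait measures estimated
    from monocular video against a gyroscope worn on the prosthetic shank.
    Includes a synthetic gait generator with known ground truth (stride-time
    variability, sensor/video clock offset, gyro noise, toe-catch glitches,
    near-edge keypoints), swing-phase detection from the shank gyroscope
    (zero-phase Chebyshev low-pass, rectification, median-filter
    deglitching), decoding of quadrature-encoded gait-event outputs from a
    video model, sensor-timebase calibration and video/sensor clock
    synchronization, cadence and walking-velocity estimation over timed
    10-m segments, one-to-one event matching with residual timing metrics,
    and keypoint-quality and edge-clipping segment filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
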