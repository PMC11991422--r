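Package: cervrom
Title: Cervical Spine Range of Motion from Head-Pose Tracking Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts timestamped head-orientation streams (unit quaternions,
    nominally 60 Hz, as recorded by a head-mounted display) into calibrated
    anatomical cervical-spine angles, segments the six-movement examination
    protocol (flexion, extension, left/right side bend, left/right rotation),
    and extracts signed range of motion, movement durations, left/right
    asymmetries and compensatory cross-plane co-movements. Includes a
    minimum-jerk session simulator with ground-truth annotations, a digital
    twin of a goniometer-instrumented skull-rig validation experiment,
    session file round-tripping, posturographic trajectory plots and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
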