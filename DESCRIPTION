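Package: ahrswim
Title: Swim Session Analysis from Trunk-Worn AHRS Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analyzes swim training sessions recorded by a trunk-worn
    attitude and heading reference system (AHRS). Segments sessions into
    laps by detecting turns and stops in the pitch angle (with median
    absolute deviation recovery of pitch-silent backstroke turns via
    heading reversal), classifies the stroke style of each lap from
    accelerometer energy features (z-axis rule for backstroke; SVM or a
    small neural network for the remaining styles), counts strokes per
    lap (roll-extrema detection for alternating-arm styles, pitch-cycle
    detection with dynamic-time-warping template rejection for
    undulating styles), and reports lap time, stroke rate, trunk
    elevation, body balance and body rotation. Includes a seeded
    synthetic-session simulator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
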