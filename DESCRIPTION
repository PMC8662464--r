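Package: pedalkin
Title: Kinematics and Load Analytics for Instrumented Ergometer Pedals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing pedalling sessions recorded by
    sensor-instrumented ergometer pedals that stream a low-rate (25 Hz)
    inertial measurement unit (three-axis accelerometer and gyroscope) and
    four inductive (LC-tank) resonance-frequency channels per pedal.
    Provides a forward simulator with known ground truth for crank angle,
    pedal angle and applied loads; zero-phase Butterworth pre-processing;
    crank-angle and cadence estimation from the acceleration magnitude;
    pedal-angle estimation by fusing accelerometer and gyroscope streams
    with a scalar Kalman filter; calibration of the resonance-frequency to
    load mapping with cross-validated LASSO regression; and post-session
    analytics including crank-phase force profiles, left-right breakdowns
    and game-control signals for interactive training.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
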