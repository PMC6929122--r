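Package: hipkin
Title: Hip Joint Kinematics from Paired Wearable Magneto-Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Estimates 3D hip joint angles from two body-worn magnetic and
    inertial measurement units (pelvis/lumbar and thigh) without requiring
    specific sensor placement or extensive calibration motions.  Implements a
    Kalman filter for sensor-to-sensor relative orientation (SSRO) that fuses
    gyroscope, accelerometer and magnetometer data under a shared magnetic
    field assumption, functional joint-center estimation from rigid-body
    kinematic constraints, hinge-axis identification for knee-center
    correction, anatomical frame construction following International Society
    of Biomechanics conventions, joint coordinate system angle extraction
    (flexion-extension, ad/abduction, internal-external rotation), agreement
    statistics (RMSE with circular wrap correction, regression slope and
    intercept, range of motion difference, drift), and a ground-truthed
    rigid-body IMU simulator so that the entire pipeline can be exercised and
    validated with synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
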