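Package: skatekin
Title: Lower-Limb Skating Kinematics from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates three-dimensional lower-limb joint angles of hockey
    skating from body-worn inertial measurement units (IMUs). Raw gyroscope,
    accelerometer and magnetometer streams are low-pass filtered, fused into
    sensor orientations with a complementary filter, aligned to anatomical
    segment frames through marker-based sensor-to-plate and sensor-to-body
    calibration, and decomposed into joint coordinate system (Grood-Suntay)
    hip, knee and ankle angles. The IMU-derived angles are validated against
    a marker-based reference by root-mean-square error, twelve calibre-
    distinctive kinematic features are extracted per stride, and high- versus
    low-calibre skaters are classified with Friedman-test feature selection
    and subject-wise cross-validated k-nearest-neighbour models (with a PCA
    variant). A synthetic-data module generates full skating cohorts with
    known ground truth (stride kinematics, virtual markers, virtual IMU
    readouts) so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
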