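Package: camptokin
Title: Continuous Camptocormia Angle Measurement from Four Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for continuous measurement of the camptocormia angle (CA),
    the forward-flexion angle of the trunk used to monitor postural
    abnormalities in advanced Parkinson's disease. Implements both the
    perpendicular method (angle of the L5-C7 spine line against the vertical,
    from a calibrated two-sensor spine-chain model) and the consensus
    malleolus method (spine line against the L5-to-lateral-malleolus line,
    obtained by adding a two-pendulum leg angle computed from thigh and shank
    accelerometers). Includes Savitzky-Golay preprocessing of the raw
    tri-axial acceleration channels, zero and patient-specific calibration,
    reconstruction of reference angles from optical motion-capture markers,
    windowed per-activity RMSE and MAD-by-angle evaluation, and a
    forward-kinematics generator that produces matched synthetic
    accelerometer and marker data from prescribed posture scripts.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
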