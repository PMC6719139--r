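Package: vcgbeat
Title: Heart Rate Monitoring and Beat Detection from Seismocardiography and Gyrocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Real-time style heart-rate monitoring and aortic-opening beat
    detection from chest-worn inertial sensor recordings. Combines
    seismocardiography (dorsoventral acceleration, aZ) and gyrocardiography
    (longitudinal-axis rotation, gX) through a windowed autocorrelation
    estimator built on an oscillation-amplifying transfer function (VarWin),
    sensor-fusion decision logic with previous-measurement feedback, and
    gyroscope cross-verification of detected beats. Includes a Pan-Tompkins
    ECG R-peak reference detector, a tolerance-window evaluation harness
    (TPR, PPV, Pearson r-squared, Bland-Altman limits of agreement), and a
    fully parameterised synthetic cardiomechanical signal simulator with
    ground-truth annotations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
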