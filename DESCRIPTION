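Package: emgkalman
Title: Continuous Kalman Decoding of Finger Joint Angles from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous estimation of multiple finger-joint angle
    trajectories from multichannel surface electromyography (sEMG) with a
    linear-Gaussian state-space model decoded by the classical Kalman
    filter. Windowed mean-absolute-value (MAV) features are the
    observations and joint angles the states; the state-transition and
    observation matrices are fitted in closed form by least squares and
    the process/observation noise covariances from the fit residuals.
    Includes sEMG preprocessing (Butterworth bandpass, sliding-window
    feature extraction), a synthetic-session and linear-dynamical-system
    simulator for fully offline testing, Pearson-correlation evaluation
    per degree of freedom, plain-text session/model/trace serialization,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
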