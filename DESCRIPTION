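Package: nmskit
Title: EMG- and IMU-Driven Neuromusculoskeletal Modelling of Elbow Muscle Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts individual elbow flexor and extensor muscle forces from
    wearable-sensor data. Estimates the elbow flexion-extension angle from a
    forearm-mounted inertial sensor with an extended Kalman filter, converts
    surface EMG to muscle excitations and activations, evaluates a Hill-type
    musculotendon model for seven elbow muscles, calibrates subject-specific
    parameters by simulated annealing against the inverse-dynamics joint
    moment, and adjusts muscle excitations within a relative tolerance so the
    estimated joint moment tracks the experimental moment. Includes
    non-negative matrix factorization muscle-synergy analysis and a
    self-consistent synthetic trial generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
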