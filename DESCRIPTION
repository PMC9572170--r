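Package: relapsekit
Title: Wearable Biosignal Phenotyping and Autoencoder-Based Relapse Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for digital phenotyping of psychotic-spectrum patients from
    consumer smartwatch streams. Provides a synthetic-cohort generator for
    multi-day accelerometer, gyroscope, RR-interval, step and sleep data with
    controllable group effects and relapse episodes; preprocessing of raw
    streams into cleaned 5-minute analysis windows; linear and nonlinear
    heart-rate-variability and actigraphy features (Lomb-Scargle band powers,
    sample entropy, Higuchi and multiscale morphological fractal dimensions,
    Poincare descriptors); nonparametric patient-versus-control comparison
    with false-discovery-rate control; autoencoder models (dense, convolutional,
    recurrent, transformer, and variational convolutional variants) trained on
    normal data with Mahalanobis and Kullback-Leibler anomaly scoring; and the
    accompanying cross-validated evaluation, severity and multimodal fusion
    protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
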