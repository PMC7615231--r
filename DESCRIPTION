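Package: sonoguide
Title: Joint Probabilistic Gaze and Probe Guidance for Obstetric Ultrasound Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-task probabilistic guidance for freehand obstetric
    ultrasound scanning. Jointly models sonographer gaze movement and
    ultrasound-probe rotation from synchronized video features, 2-D gaze
    points, and 4-D unit quaternions, using a modality-aware graph shared
    between two graph-convolutional gated recurrent streams coupled by a
    bidirectional hidden-state pathway. Predictions are densities (bivariate
    Gaussian gaze shifts, Gaussian-mixture gaze centers, 4-D Gaussian
    quaternion rotations) trained by joint negative log-likelihood with a
    unit-norm quaternion prior. Includes quaternion geometry, sliding-window
    gaze fixation clustering, saliency-map evaluation metrics (SIM, CC, KLD,
    AUC-Judd, NSS), rotation-direction accuracy with coarse/fine staging,
    and a synthetic scan simulator that generates synchronized
    gaze/probe/feature streams for training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
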