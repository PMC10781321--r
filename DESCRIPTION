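Package: fogbci
Title: Motor-Imagery EEG Command Decoding with a Convolutional LSTM
    Autoencoder and Fog-Latency Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding four-class motor-imagery EEG (left foot,
    left hand, relaxation, mental arithmetic) recorded from a 4-electrode
    consumer headset (TP9, AF7, AF8, TP10) into machine commands. A
    convolutional LSTM autoencoder, implemented and trained in R, compresses
    each trial into a 16 x 21 latent image; a random forest classifies the
    flattened image into a command, and can be benchmarked against support
    vector machine, decision tree and gradient boosting baselines. Includes
    a seeded synthetic EEG generator with event-related
    desynchronization/synchronization band structure, Butterworth band-pass
    preprocessing, per-pixel Gini importance maps of the latent space, and a
    discrete-event simulation comparing command latency of fog-node versus
    cloud-only processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    rpart,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
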