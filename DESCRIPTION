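Package: ctgkit
Title: Cardiotocography Signal Simulation, Preprocessing and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for classifying 20-minute fetal heart rate (FHR)
    recordings from cardiotocography as normal or abnormal. Provides a
    synthetic FHR trace generator with realistic signal-loss and spike
    artifacts, a four-stage preprocessing pipeline (missing-value
    quality control, linear-interpolation gap repair, spike
    stabilization, Savitzky-Golay smoothing), rasterization of traces
    into fixed-geometry monochrome images, small VGG-style convolutional
    network builders (MKNet-A/B/C) and a recurrent (LSTM) builder
    (MKRNN) with a self-contained training engine, feature-based SVM
    and random-forest baselines, and a cross-validated ROC/AUC
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    signal,
    e1071,
    randomForest,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
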