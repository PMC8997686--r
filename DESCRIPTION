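Package: bcgnet
Title: Hypertension Screening from Ballistocardiogram Signals with
    Wavelet Scalograms and a Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for automated hypertension screening
    from single-channel ballistocardiogram (BCG) recordings. Recordings
    are z-score normalized, segmented into fixed 30 second epochs,
    transformed into time-frequency scalogram images with an analytic
    generalized Morse wavelet filter bank, and classified with a
    24-layer 2D convolutional neural network trained by backpropagation
    with Adam and L1 kernel regularization. Includes a synthetic BCG
    generator that emulates the lettered G-N deflection morphology of
    the cardiac beat, respiratory amplitude modulation, heart-rate
    variability and hypertensive amplitude instability, so the whole
    pipeline can be exercised without access to clinical recordings;
    hold-out and k-fold cross-validation evaluation with the standard
    binary diagnostic metric suite; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    optparse,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
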