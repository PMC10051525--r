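Package: ecgnet
Title: 1D Convolutional Networks for ECG Heartbeat and Rhythm Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrocardiogram (ECG) beat and rhythm classification
    with a lightweight one-dimensional convolutional network built around
    evolving normalization-activation (EvoNorm) layers, squeeze-and-excitation
    channel gates, multiplicative residual blocks, focal/cross-entropy losses,
    and a gradient-clipped Adam training protocol. Includes beat extraction
    from raw recordings (R-peak windowing to fixed-length 187-sample beats),
    an FIR four-channel transform with sliding-window segmentation for atrial
    fibrillation detection, stratified cross-validation and oversampling
    utilities, confusion-matrix metrics, a labelled synthetic ECG generator
    so that every stage is testable without external downloads, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
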