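Package: bnncode
Title: Spatiotemporal Image-to-Pulse Encoding and Spike-Train Decoding
    for In Vitro Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a biomimetic visual-information encoding pipeline for
    cultured (in vitro) biological neural networks on high-density
    microelectrode arrays: a small convolutional feature extractor that
    compresses a colour image into eight 5x5 normalized feature maps, a
    delayed-phase pulse encoder that turns the maps into eight biphasic pulse
    sequences aligned to subthreshold-membrane-oscillation peaks, a synthetic
    spike-train simulator standing in for the living culture, a multinomial
    logistic-regression decoder (iteratively reweighted least squares) over
    binned evoked responses, and a spike-time-tiling-coefficient (STTC)
    functional-connectivity analysis with consensus modularity, within-module
    degree z-scores and participation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
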