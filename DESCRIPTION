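Package: didi
Title: Dynamic Influence Data Inflation for Directed EEG Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inflates multichannel EEG recordings into directed pairwise
    influence signals by constrained autoregressive decomposition: each
    channel is reduced to its univariate innovation process, and for every
    ordered electrode pair the part of the innovation predictable from the
    influencing channel's history is extracted as a directed influence
    signal.  The resulting M x M x T array can be classified with a compact
    convolutional network (a depthwise-separable architecture in the EEGNet
    family, implemented here with exact input gradients), and classification
    decisions are explained as time-resolved directed connectivity support
    maps rendered on a 10-20 electrode montage.  Includes Granger causality
    and windowed Granger causality, a coupled-VAR simulator with planted
    time-switching couplings for validation, an EDF reader, epoching and
    average-rereference preprocessing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
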