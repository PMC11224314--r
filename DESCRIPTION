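Package: tscanet
Title: Temporal-Spatial Cross-Attention Networks for Imagined-Character Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements TSCA-Net, a temporal-spatial cross-attention network
    for classifying imagined handwritten characters from multichannel
    intracortical spiking activity. Provides the four network blocks
    (temporal-feature LSTM+Transformer stream, spatial-feature stream, two
    temporal-spatial cross-attention blocks, and a pooled classifier) with
    four position-embedding variants, a reverse-mode automatic
    differentiation engine with Adam training, stratified five-fold
    cross-validation with macro-averaged confusion-matrix metrics, the full
    component / position-embedding / heads-dims ablation machinery, a
    synthetic microelectrode-array trial generator for end-to-end testing,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
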