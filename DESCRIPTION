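Package: wmdecode
Title: Population Decoding and Tuning Analyses for Spatial Working-Memory
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode prefrontal recordings in a
    nine-location spatial working-memory task with a drug-injection design
    (pre / early-post / late-post periods). Provides single-unit spatial
    tuning statistics with balanced-subsample ANOVA, ranked-tuning slopes,
    spike density functions and polynomial surface fits; cross-validated
    support-vector decoding of remembered target location with greedy
    ensemble construction, class balancing and label-shuffle nulls; the
    decomposition of binary decodability into population signal and
    projected precision with its theoretical accuracy and a
    shrinkage-regularized linear-discriminant empirical counterpart;
    spike-waveform width classification into narrow- and broad-spiking
    cells via mixture modelling; behavioral performance and
    trajectory-dispersion analyses; gaze-control analyses; and a synthetic
    session generator with ground truth so every stage can be exercised
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
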