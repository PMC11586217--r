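Package: laicast
Title: Change-Point-Aware BiLSTM Forecasting of Alfalfa Leaf Area Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and forecasting the leaf area index (LAI) of
    multi-cut forage crops such as alfalfa. Implements the three classical
    sigmoidal growth models (Logistic, Richards, Gompertz) for relative LAI
    with bounded multi-start nonlinear least squares, moving-sum (MOSUM)
    change-point detection of cutting events, change-point-aware sampling of
    contiguous training windows, and an attention-based bidirectional LSTM
    encoder-decoder regressor trained with Adam, together with a seeded
    simulator of multi-cut growing seasons so the full pipeline runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
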