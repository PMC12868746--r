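Package: topoforecast
Title: Topological Forecasting of EEG Persistence Images with
    Graph-Attention Adversarial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns band-decomposed EEG windows into high-order persistence
    images via delay embedding and Vietoris-Rips persistent homology, and
    forecasts the next-window image with an adversarially trained generator
    built from graph-attention layers, an LSTM over the flattened pixel
    sequence and a sigmoid head. Includes a seeded synthetic-EEG cohort
    simulator with plantable clinical-score relations, pixelwise AUC/MAP/MAE
    evaluation, GAT-only and LSTM-only ablation variants, subject-level
    classification readouts, and a convolutional image-quality regressor
    whose per-sample outputs are correlated with clinical severity scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    rlang,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
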