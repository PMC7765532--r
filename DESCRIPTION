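Package: p300cca
Title: Single-Trial P300 Decoding with CCA Spatial Filters and Shrinkage LDA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for single-trial classification of target versus
    non-target responses in visual oddball (P300) brain-computer interface
    experiments. Provides a protocol-faithful synthetic oddball-session
    generator with known ground truth, a BIDS-flavoured on-disk session format
    (BrainVision dialect), epoch extraction with three-criterion artifact
    rejection and zero-phase FIR band-pass filtering, canonical-correlation
    spatial filters learned from target-epoch averages, linear discriminant
    analysis with automatic (Ledoit-Wolf style) covariance shrinkage and
    forward-backward stepwise feature selection, five-fold cross-validated
    balanced accuracy, permutation-based chance levels, kernel-density ERP
    significance testing, cross-condition transfer evaluation, and the
    aggregation arithmetic used to summarise per-participant accuracy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
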