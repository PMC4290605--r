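Package: sumosite
Title: Sumoylation Site Prediction from Lysine-Centered Sequence Windows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts sumoylation sites on protein lysines from
    7-residue sequence windows. Encodes each candidate lysine with 137
    features (positional one-hot composition, Hopp-Woods hydrophilicity,
    consensus-motif and charge flags, conformational flexibility and
    intrinsic disorder, terminal position and protein length, Kharakoz
    sub-window volumes), ranks features by distance-weighted ReliefF,
    and classifies with a class-weighted RBF support vector machine
    tuned by exponential grid search with decision-value thresholds.
    Includes the consensus-motif regular-expression baseline scanner,
    chi-square / Mann-Whitney statistical screening with
    Benjamini-Hochberg correction, repeated stratified cross-validation
    with averaged ROC curves, and a synthetic-data generator that
    plants the reported positional enrichments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
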