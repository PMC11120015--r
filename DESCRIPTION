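Package: npulud
Title: Neighborhood-Based Positive-Unlabeled Learning with Decision Trees
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binary classification from positive and unlabeled data.
    Unlabeled instances are first relabeled by a unanimous-vote k-nearest-
    neighbor rule (an instance whose k nearest neighbors are all labeled
    positive is promoted to the positive class, all others are assigned
    negative), and an entropy-based decision tree is then trained on the
    completed labels. Includes readers for CSV and ARFF tabular data, a
    seeded label-masking utility, stratified k-fold cross-validation of the
    full pipeline, confusion-matrix metrics, an exact paired Wilcoxon
    signed-rank comparison, seeded synthetic data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    foreign,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
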