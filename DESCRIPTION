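Package: protstab
Title: Sequence-Based Protein Stability Scoring, Generation, and Refinement
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence-only modelling of mini-protein stability as
    measured by high-throughput protease-resistance assays. Implements an
    unfolded-state model (per-protease convolutional predictor trained on
    scrambled sequences) and the derived stability score, a multi-task
    convolutional evaluator with bespoke loss terms including a
    grammar-kernel secondary-structure validity penalty, a secondary-to-
    primary sequence generator with attention and beam decoding, constrained
    beam-search refinement of designs, a fourteen-type sequence perturbation
    suite, cross-chip assay calibration by orthogonal and piecewise-linear
    orthogonal regression, and a synthetic corpus generator so that every
    stage can be trained and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, Rcpp, Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
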