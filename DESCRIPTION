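Package: mongooseFS
Title: Binary Dwarf Mongoose Optimization for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper-based feature selection for high-dimensional
    classification data (for example microarray gene-expression matrices with
    few samples and thousands of features) using a binary adaptation of the
    dwarf mongoose optimization metaheuristic. Candidate feature subsets are
    encoded as continuous positions in the unit box, thresholded to binary
    masks, and scored by the k-nearest-neighbour classification error rate
    under stratified k-fold cross-validation. The package provides the
    population-based optimizer (alpha-group foraging, sleeping-mound
    accounting, scout movement, babysitter exchange), the feature-selection
    wrapper with hold-out validation metrics, a synthetic high-dimensional
    data generator for controlled experiments, a multi-run benchmarking
    harness with Friedman mean ranks and Wilcoxon signed-rank comparisons,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    foreign,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
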