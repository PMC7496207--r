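Package: cellvote
Title: Supervised Cell-Type Classification of Single-Cell Transcriptomes
    with a Voting Ensemble and Few-Sample Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates query single-cell RNA-seq profiles against a labeled
    reference. Genes are ranked by a dropout-residual score that combines the
    residual of log mean expression regressed on the per-gene dropout rate
    with an entropy-like residual against the mean of log expression. Rare
    ("few-sample") cell types, those comprising at most 0.5 percent of the
    reference, are handled by a pairwise learner: cell pairs labeled by
    class identity train a gradient-boosted tree regressor whose pair
    predictions are aggregated per class with Pearson-correlation weights.
    Remaining cells are classified by ten small multilayer perceptrons
    trained on bootstrap resamples, voting with a confidence threshold;
    cells no classifier is confident about are reported as unassigned.
    Includes Cohen's kappa / assigned-rate evaluation over assigned cells,
    stratified self-projection cross-validation, and a negative-binomial
    zero-inflation simulator with a sparsity-corruption operator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    methods,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
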