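Package: hsptier
Title: Two-Tier Kernel Classification of Heat Shock Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based identification of heat shock proteins (HSPs) and
    assignment to the six canonical chaperone families (HSP20, HSP40, HSP60,
    HSP70, HSP90, HSP100) from primary amino-acid sequence alone. Protein
    sequences are encoded as 20-dimensional amino-acid composition or
    400-dimensional coupled (dipeptide) composition percentage vectors and
    classified by a two-tier stack of soft-margin kernel support vector
    machines: a gate model separating HSPs from non-HSPs, then six
    one-vs-rest family models whose decision values are resolved by argmax.
    Includes stratified five-fold and leave-one-out cross-validation with
    sensitivity/specificity/accuracy/MCC/ROC-AUC reporting, grid search over
    kernel hyper-parameters, per-residue compositional enrichment analysis
    with bootstrap significance, and a seeded first-order Markov-chain
    sequence simulator for fully self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
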