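Package: screcap
Title: Quantifying How Well Disease Models Recapitulate Human Disease at Single-Cell Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative single-cell transcriptomics between a human condition
    and its disease models. Per pathway, a sparse multi-block partial least
    squares discriminant analysis (one block per cell type, quantile-based
    adaptive sparsity) is trained on human pseudobulk profiles to score how
    strongly the pathway separates disease from control. Disease-model
    log2 fold changes, gated on significance and restricted to one-to-one
    orthologs and mapped cell types, are then injected into the control
    samples as an in-silico treatment; the score shift of the treated samples
    under the fixed human model, expressed as a percentage of the human
    reference shift, quantifies recapitulation at pathway, cell-type and gene
    level. Includes a permutation validity test, cell and gene importance
    projections with significance testing, and a synthetic-data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
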