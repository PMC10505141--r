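Package: pseudomix
Title: Pseudobulk Mixture Simulation and Compositional Benchmarking of
    Tumour Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for bulk RNA-seq cell-type
    deconvolution in the tumour microenvironment. Generates synthetic
    annotated single-cell corpora, balances minority cell types per
    patient with SMOTE interpolation, simulates artificial bulk mixtures
    of 500 single cells with known ground truth under sparse,
    fixed-tumour-purity and lineage-granular designs, builds single-cell
    reference and signature matrices, provides a non-negative
    least-squares deconvolution baseline plus an adapter contract for
    external methods, and scores predictions with compositional
    (Bray-Curtis, Aitchison) and cell-type-specific (RMSE, Pearson, raw
    error, relative proportion error, false-positive/false-negative)
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
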