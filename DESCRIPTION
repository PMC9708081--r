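Package: commonspace
Title: Cross-Species Transcriptomic Common Spaces for Mouse-Human Brain
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds comparable mouse and human brain-region expression
    representations from homologous genes and sharpens them with a
    supervised latent embedding: a fully connected brain-region classifier
    is trained on voxel-wise expression and its output layer is removed,
    leaving the last hidden layer as a latent common space. Provides atlas
    ontology aggregation, expression preprocessing (log2 transform,
    replicate averaging, missingness filtering, K-nearest-neighbour
    imputation, two-step normalization), region-by-region Pearson
    similarity matrices and rank-based locality and homology criteria,
    ensembles of repeated trainings, Bernoulli and binomial evaluation
    statistics with FDR control, Ward hierarchical clustering with scree
    and elbow selection, integrated-gradients gene attribution, and a
    synthetic two-species data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    lme4,
    lmerTest,
    RNifti,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
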