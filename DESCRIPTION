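Package: drpred
Title: Composable Deep Learning Models for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A modelling toolkit for predicting drug sensitivity (ln-IC50, AUC,
    ActArea) of cancer cell lines from drug structures and cell omics profiles.
    Drugs enter as SMILES strings and are featurized as circular fingerprints,
    token sequences, or molecular graphs; cells enter as expression, pathway
    enrichment, mutation, or copy-number profiles. A registry of nine drug
    encoders, nine cell encoders, and two fusion modules (pooled feed-forward
    and multi-head attention) enumerates 135 buildable model configurations.
    Includes leakage-controlled dataset splitting (random, leave-cell-out,
    leave-drug-out, strict), a seeded training loop with MSE/R-squared/Pearson
    evaluation, a denoising-autoencoder pretrainer for expression profiles, a
    benchmark harness, and a synthetic fixture generator. Neural networks run
    on a built-in reverse-mode automatic-differentiation engine over base R
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    fgsea,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
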