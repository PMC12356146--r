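Package: snpsieve
Title: Feature Selection and Deep-Learning Classification for SNP
    Case/Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting binary disease status
    from SNP genotype panels. Reads GEO-style genotype/phenotype CSV
    pairs, cleans them (invariant-SNP removal, No-Call filtering, modal
    imputation), converts genotypes to per-SNP case-proportion (mean)
    encodings with both leakage-safe fold-fitted and whole-dataset
    modes, ranks and selects SNPs with an arithmetic-geometric-mean
    relevance filter plus cosine-redundancy removal alongside ReliefF,
    CMIM + SVM-RFE, autoencoder-L1, chi-squared and mutual-information
    alternatives, trains a zoo of compact neural classifiers (MLP,
    autoencoders, GRU, Bi-LSTM, CNN, ResNet, stacked variants) on the
    selected panel, and evaluates everything with stratified five-fold
    cross-validation reporting accuracy, sensitivity, specificity and
    F1. Includes a seeded synthetic-genotype simulator with planted
    causal SNPs for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
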