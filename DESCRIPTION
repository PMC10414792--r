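Package: pepstack
Title: Stacked Convolutional Ensembles for Neuropeptide Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short peptides (5-100 residues) as neuropeptides or
    non-neuropeptides with a stacked ensemble: four sequence encoders (positional
    one-hot with a uniform pad vector, 14 AAIndex physicochemical properties,
    g-gap dipeptide composition, and skip-gram residue embeddings) each feed a
    compact one-dimensional convolutional base classifier, and a Gaussian naive
    Bayes meta-learner combines the four out-of-fold base probabilities.
    Includes standard binary-classification evaluation (sensitivity,
    specificity, accuracy, Matthews correlation, ROC AUC), a stratified
    cross-validation harness, exact Shapley-value attribution over the four
    meta-features, and a synthetic peptide generator with a plantable sequence
    motif for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    tidyr,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
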