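Package: lncsieve
Title: Alignment-Free Classification of Long Non-Coding RNAs and mRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Distinguishes long non-coding RNAs (lncRNAs) from messenger RNAs
    using only the transcript itself: sequence-intrinsic features (GC content,
    Fickett TESTCODE score, four open-reading-frame typologies with length,
    coverage, hexamer and relative-codon-bias scores), secondary-structure
    features derived from dot-bracket folds (minimum free energy, paired
    ratio, loop decomposition, and joint sequence-and-structure k-mer
    log-likelihood scores), and physicochemical features of the putative
    translated proteins. Features feed a gradient-boosted tree classifier
    trained with z-score standardisation, SMOTE minority over-sampling and
    recursive feature elimination with cross-validation. Includes a
    deterministic synthetic transcript generator so the full pipeline can be
    exercised without external data, and a command-line interface for
    training, prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    parallel,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
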