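Package: pampaqsar
Title: Two-QSAR Modeling of PAMPA Effective Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts and interprets PAMPA (parallel artificial membrane
    permeability assay) effective permeability, log Pe, from molecular
    descriptors with a two-QSAR workflow: a hierarchical support vector
    regression (HSVR) ensemble for prediction and a partial least squares
    (PLS) model for interpretation. Includes descriptor curation,
    centering-and-scaling normalization, correlation screening, ion-class
    assignment from pKa profiles, Kennard-Stone train/test partitioning,
    PCA chemical-space projection, genetic-algorithm and recursive-
    feature-elimination descriptor selection, the full suite of internal
    and external validation statistics (rm2 family, qF1-qF3, concordance
    correlation coefficient, 10-fold cross-validation, Y-scrambling),
    stringent-criteria checking, permeability rule screens, and a
    synthetic-data generator for end-to-end testing.
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
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
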