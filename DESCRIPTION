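Package: ramanboost
Title: Incremental Boosted SVM Ensembles for Raman Concentration Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for threshold classification of analyte concentration from
    Raman spectra with an incremental, boosting-style ensemble of soft-margin
    support vector machines. New measurement batches extend a trained ensemble
    without access to earlier data and without discarding earlier hypotheses.
    Includes a synthetic ethanol-water Raman spectrum simulator (dilution
    series, Gaussian bands, glass background, shot-limited noise), interval
    derivative/integral feature extraction with water-background subtraction,
    RBF-kernel C-SVM base learners tuned by Nelder-Mead search on
    cross-validated AUC-ROC, and a nested leave-one-experiment-out evaluation
    driver reporting per-threshold accuracy, precision and sensitivity.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
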