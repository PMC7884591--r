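Package: dockcal
Title: Similarity-Calibrated Hybrid Docking Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recalibrates docking scores of query compounds against a set of
    reference ligands with experimentally measured binding affinities. The
    correction factor is a similarity-weighted mean of the reference ratios
    between experimental binding free energy and docking score, with weights
    given by a Tanimoto similarity raised to an integer exponent (the compound
    similarity effect function). Includes OpenBabel 2D fingerprints (FP2, FP3,
    FP4, MACCS) via ChemmineOB, Ki/Kd to free-energy conversion, scoring and
    screening metrics (RMSE, MAE, R-squared, predictive index, enrichment
    factor, ROC AUC), a repeated-split benchmark harness with Tc-range library
    scenarios, and a synthetic compound-set generator with cluster-correlated
    docking-score bias for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
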