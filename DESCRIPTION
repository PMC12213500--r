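Package: qealike
Title: Quantitative Estimate of Algicide-Likeness Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-descriptor desirability functions to a reference set of
    algicidal compounds and scores arbitrary molecules with a quantitative
    estimate of algicide-likeness (QEA), a geometric-mean aggregate in the
    QED family of likeness scores. Includes descriptor calculation from
    SMILES/SDF input (molecular weight, logP, hydrogen-bond acceptors and
    donors, rotatable bonds, aromatic rings), optimal histogram binning by
    cost minimisation, nonlinear least-squares desirability curve fitting,
    ROC/AUC decoy evaluation, EPA aquatic acute-toxicity categorisation,
    and a synthetic descriptor simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
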