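Package: hirrecur
Title: Hepatic Injury/Regeneration Signatures and Recurrence Prediction for HCC
Version: 0.1.0
Authors@R: person("HIR", "Maintainers", email = "maintainers@hirrecur.org", role = c("aut", "cre"))
Description: Derives hepatic injury/regeneration (HIR) gene-expression
    signatures from paired pre/post-injury liver datasets using the
    random-variance t-test with a permutation global test, classifies
    hepatocellular carcinoma patients into HIR and quiescent (QT) subgroups
    with a Bayesian compound covariate predictor (with leave-one-out
    cross-validation), applies weighted Cox-score risk classifiers and
    integrates two predictors into three risk strata, performs
    recurrence-free survival analysis with early/late landmark windows,
    and reduces signatures to compact predictors via nearest shrunken
    centroids and univariate-screen plus backward-stepwise selection.
    Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
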