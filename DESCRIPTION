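Package: rethinktox
Title: Multi-Label Prediction of Drug-Induced Organ Pathology from
    Dose-Response Toxicogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting drug-induced histopathological findings in
    liver and kidney from gene-expression dose-response profiles.  Fits
    per-gene sigmoid dose-response curves across three dose levels and
    extracts the maximal response (R_max) as the feature; balances sparse
    correlated pathology label sets with an improved multi-label SMOTE that
    never emits all-negative synthetic samples; ranks genes by a multi-label
    F statistic and selects subsets with a size-penalised fitness function;
    and fits an attention-weighted recurrent "rethinking" network
    (Att-RethinkNet) that refines its multi-label predictions over T
    iterations, alongside binary-relevance, classifier-chain and per-label
    k-NN baselines.  Includes the full multi-label evaluation suite (subset
    accuracy, Jaccard pair accuracy, per-label accuracy, macro
    sensitivity/specificity/F1, micro ROC/AUC), a K-fold cross-validation
    driver, and a synthetic data generator emulating the structure of
    Open TG-GATEs extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
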