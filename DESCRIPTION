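Package: ielnet
Title: Evolutionary Deep Learning for Predicting Adolescent Externalizing Disorder Onset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting the onset of
    adolescent externalizing disorders (ADHD, oppositional defiant disorder,
    conduct disorder) from high-dimensional multimodal cohort data. Provides a
    synthetic cohort generator with a liability-threshold outcome model and
    planted predictors; case-control sample construction from thresholded CBCL
    subscale T-scores with age/sex matching and new-onset labelling; a staged
    feature-preprocessing stack (missingness filtering, one-hot encoding,
    outlier trimming, min-max scaling, masked non-negative matrix factorization
    imputation, feature agglomeration); coarse feature selection via
    association filters and BIC-tuned LASSO; Integrated Evolutionary Learning
    (IEL), a population-based metaheuristic that jointly evolves learning
    hyperparameters and feature subsets against a Bayes Information Criterion
    fitness with a recursive warm restart; a feed-forward neural network
    classifier trained with AdamW and early stopping under stratified k-fold
    cross-validation; and held-out evaluation with ROC/AUROC, Shapley-value
    feature importances, and accuracy-importance correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
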