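Package: hfnet
Title: Heart-Failure Risk Prediction from Comorbidity Networks and Stacked Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the risk of progression to heart failure in patients with
    ischemic heart disease from routinely collected hospital discharge records.
    Builds directed personal disease networks (PDN) from each patient's ICD-10
    admission history, aggregates them into cohort baseline networks (BDN),
    derives a disease-specific network (DSN) of case-vs-control specificity
    weights, and extracts three network similarity features (node, edge and
    PageRank-weighted rank scores). These features, together with age and sex,
    drive DXLR, a two-stage stacking ensemble (decision tree, gradient-boosted
    trees and leaf-wise gradient-boosted trees feeding out-of-fold
    probabilities plus crucial features to a random-forest meta learner).
    Includes a synthetic administrative-data generator, the full repeated-split
    evaluation protocol with SMOTE class balancing, feature-ablation and
    subgroup analyses, and Shapley-value feature attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    xgboost,
    randomForest,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
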