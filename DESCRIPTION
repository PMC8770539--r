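Package: methorigin
Title: Epi-Driver Gene Discovery and Methylation-Based Tissue-of-Origin Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pan-cancer integration of DNA methylation (HM450-style beta values)
    and RNA-seq count data to nominate epi-driver genes and trace the tissue of
    origin of carcinomas of unknown primary. Implements probe-level quality
    filtering and KNN imputation, rank-sum differential methylation with
    delta-beta gating, a moderated differential-expression test on log2 CPM,
    co-expression module detection, directed metabolic and protein-interaction
    networks with the Score_A importance statistic, region-stratified
    CpG-expression linear models with a permutation null, two-stage
    tissue-specific marker selection (one-vs-rest filter, gradient-boosted
    Shapley ranking, plateau panel sizing), and an under-sampled one-vs-rest
    random-forest origin classifier. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable without external
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
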