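Package: miniabs
Title: Absolute Single-Sample Breast Cancer Subtyping from Pairwise Gene
    Expression Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a minimal-gene-panel absolute single-sample
    classifier for the five intrinsic breast cancer subtypes (Basal-like,
    Her2E, LumA, LumB, Normal-like). Features are slack-thresholded pairwise
    log2 expression ratios (PGERs) computed within each sample, so subtype
    calls do not depend on cohort composition or between-sample
    normalisation. Includes the full construction pipeline: one-vs-rest
    Wilcoxon rank-sum selection of subtype-specific differentially expressed
    genes with Benjamini-Hochberg correction, stepwise seed-plus-level gene
    set assembly, cross-validated training over four learners and a slack
    margin grid, Gini-importance gene ranking with stepwise panel reduction,
    an ensemble majority-vote prediction rule over the slack margin grid, and
    evaluation by accuracy and Cohen's kappa with and without the Normal-like
    subtype. A synthetic five-class expression simulator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
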