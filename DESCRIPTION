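Package: oralcyto
Title: Automated Oral Cytology Segmentation, Scoring and Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automated risk stratification of oral
    brush-cytology specimens imaged on portable field microscopes. Provides a
    seeded synthetic cytology generator (circular field-of-view images with
    stained cells, clumps and shadow artifacts, plus score cohorts with
    class-conditional statistics), circular field-of-view estimation and
    watershed-based cell segmentation, a four-stage cell quality-control
    cascade, a pluggable per-cell atypia scoring contract with a trainable
    morphometric reference scorer, per-patient aggregation of cell scores,
    a two-test cascade classifier separating carcinoma from high-grade
    dysplasia and low-grade/benign lesions, and the diagnostic statistics
    used to evaluate such models (sensitivity/specificity/accuracy, predictive
    values, Cohen's kappa, McNemar's test, ROC with Youden cutoff).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    png,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
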