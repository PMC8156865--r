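Package: elasticgrade
Title: Entropy-Gated Elastic Ensembles for Patch-Based Microscopy Image Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades microscopy images (e.g. H&E-stained breast carcinoma
    sections) with an elastic ensemble of patch-context classifiers. An image
    is tiled into a patch grid, per-patch feature maps are combined into
    multi-level contextual groupings, and each ensemble member emits a class
    probability distribution. Members are gated per image by the Shannon
    entropy of their output against a threshold (beta): only confident members
    are aggregated by soft voting, and images with no confident member are
    abstained for manual review. Includes coverage-aware evaluation metrics
    (weighted average accuracy over included images and abstain percentage),
    stratified cross-validation, beta-sweep curves, a synthetic image and
    mock-member generator for end-to-end testing without trained networks,
    and a command-line interface.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
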