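Package: wolfselect
Title: Grey Wolf Optimization for Wrapper Feature Selection and Leaf-Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary wrapper feature selection with the grey wolf optimizer (GWO)
    and a modified variant (MGWO) that combines an exponential decay of the
    exploration parameter, iteration-dependent variable weights on the three
    leader wolves, and chaotic logistic-map population initialization. Candidate
    feature subsets are scored by k-nearest-neighbour classification error under
    stratified k-fold cross-validation combined with the selected-subset
    fraction. The package also provides the surrounding image-classification
    pipeline (image-statistics or plug-in deep-feature extraction, MGWO
    selection, support vector machine classification), confusion-matrix
    metrics with cross-dataset macro averages, and synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    e1071,
    png,
    EBImage,
    optparse,
    digest
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
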