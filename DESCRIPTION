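Package: mcclassify
Title: Segmentation and Classification of Microcalcification Clusters in
    Mammogram Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis pipeline for clustered
    microcalcifications (MCs) in 2-D mammogram patches: wavelet-based
    contrast enhancement guided by a scalar sharpness index, MC candidate
    segmentation by local background estimation, percentile thresholding
    and morphological cleanup, clinical cluster rules (at least three MCs
    per square centimetre block), Dice-based segmentation evaluation
    against radiologist outlines, a 51-slot shape/size/texture feature
    descriptor, correlation-based feature selection with best-first
    search, and benign/malignant classification by majority-vote
    ensembles and stacked generalization over nine base learners with
    cross-validated reporting.  A synthetic-phantom generator provides
    ground-truth patches so the whole chain is testable without clinical
    image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    grDevices,
    jsonlite,
    nnet,
    png,
    pracma,
    randomForest,
    rpart,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
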