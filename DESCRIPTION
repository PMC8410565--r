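Package: ctcflow
Title: Circulating Tumor Cell Detection, Enumeration and Single-Cell Copy
    Number Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated workflow for image-based detection of circulating
    tumor cells (CTCs) in multi-channel immunofluorescence fields: simulation
    of stained fields with ground truth, illumination correction and Otsu
    segmentation of nuclei, per-object feature extraction and debris
    filtering, marker gating (DAPI+/CK+/CD45-) combined with a five-family
    supervised classifier protocol (stochastic gradient boosting, AdaBoost,
    SVM, random forest, extreme gradient boosting), per-sample CTC and
    circulating-tumor-microemboli enumeration, analytical-validation and
    cohort-level diagnostic and recurrence statistics, and single-cell
    copy-number profiling from low-pass binned read counts with GC
    correction, changepoint segmentation, integer copy-number calls,
    coverage-uniformity quality metrics and driver-gene annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    randomForest,
    e1071,
    xgboost,
    rpart,
    survival,
    pROC,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
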