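Package: visseq
Title: Voxel-Wise Encoding and Bidirectional Recurrent Decoding of Visual
    Categories from fMRI Response Amplitudes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage decoding of visual stimulus categories from fMRI
    response amplitudes in human visual cortex. Stage one fits voxel-wise
    sparse linear encoding models with regularized orthogonal matching
    pursuit (ROMP), scores them by held-out Pearson correlation, and selects
    the best feature layer and the most predictable voxels per visual area
    (V1, V2, V3, V4, LO). Stage two treats the five areas' selected voxel
    vectors as an ordered space sequence and classifies it with a
    bidirectional LSTM trained end-to-end under a multiclass focal loss,
    alongside classical baselines (decision tree, random forest, AdaBoost,
    linear and RBF SVM) and a fully connected network. Includes a synthetic
    data generator with a nested 5/10/23 category hierarchy, per-area
    marginal and cross-area relational category signals, an evaluation
    protocol (repeated runs, Welch tests, normalized confusion matrices),
    and a text-based dataset/pipeline layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
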