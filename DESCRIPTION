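Package: lesionBAI
Title: Lesion-Aware Brain Age Modeling and Glioma-Related Epilepsy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a lesion-aware brain-age framework for glioma: a 3D
    residual convolutional regressor that predicts age from lesion-excluded
    T1-weighted volumes via ROI-Align pooling, linear bias correction of the
    predicted age, the normalized Brain Age Index (BAI), radiomic feature
    extraction and a Mann-Whitney / Spearman / LASSO selection chain, and a
    gradient-boosting plus logistic stacking model that predicts
    glioma-related epilepsy. Ships a synthetic phantom generator so the whole
    pipeline is exercisable end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
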