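Package: boneprox
Title: Bone-Proximity Detection from Through-Needle Viscoelastic Probing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates, featurizes, and classifies viscoelastic probe events
    collected through an epidural needle as it advances toward bone. Provides
    a lumped spring-dashpot tissue simulator whose effective stiffness rises
    near bone, feature extraction (statistical moments and FFT magnitudes over
    canonical subsequence windows), sequence sampling and multiprobe window
    compilation, three classifier families (linear SVM, random forest, and a
    gradient-boosted distance regressor) under split and leave-one-group-out
    training regimes, and an evaluation layer computing first-positive
    detection depths, signed detection errors, error summaries, learning
    curves, a directionality-classification protocol, and a closed-form
    random-guess baseline.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
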