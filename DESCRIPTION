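Package: CytoSelfTrain
Title: Semi-Supervised Self-Training for Single-Cell Cytology Image
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a semi-supervised self-training framework for
    classifying small single-cell cytology images (e.g. Feulgen-stained
    cervical cell crops) when labeled data are scarce. The pipeline screens
    images by the SMD2 grey-variance-product focus measure, recovers blurry
    images with regularized deconvolution, pseudo-labels unlabeled images by
    confidence-weighted fusion of an ensemble of classifiers under a decaying
    trust threshold, and rebalances class counts using integrated optical
    density (a DNA-ploidy proxy) and centered cosine similarity. A seeded
    synthetic cell-image generator provides labeled toy data with the
    morphological and optical structure the method assumes, so every stage is
    testable without private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Classification, CellBiology, Software
RoxygenNote: 7.3.3
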