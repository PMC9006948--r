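Package: histocross
Title: Cross-Organ Histological Similarity from Patch Classifiers and
    Attention Morphometry
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of cross-organ histological similarity
    from tissue patch images.  Trains per-organ cancer-versus-normal
    convolutional patch classifiers, evaluates every model on every
    organ's held-out test split to build a cross-inference matrix of
    accuracy, AUC and F1, localizes the image evidence behind each
    prediction with gradient-weighted class activation maps (GradCAM),
    quantifies attention overlap between models by bounding-box IoU and
    pixel Jaccard index, segments nuclei inside high-attention regions
    by hierarchical multilevel thresholding, and compares nucleus shape
    and inter-nucleus density features between model pairs with
    two-sample t-tests.  A parametric generator of histology-like patch
    images with known nucleus ground truth makes the whole pipeline
    testable without whole-slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jsonlite,
    igraph,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
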