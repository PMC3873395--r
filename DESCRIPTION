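Package: cooctex
Title: Texture Descriptors Extracted from the Gray-Level Co-Occurrence Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Texture image classification built around the gray-level
    co-occurrence matrix (GLCM). Implements the classical 13 Haralick
    statistics together with several descriptor families that treat the
    co-occurrence matrix itself as the object of analysis: gray-level
    run-length indicators computed on the GLCM, level-curve shape features
    obtained by slicing the matrix as a 3D surface, circular-mask curvature
    histograms of the level-curve contours, and direct PCA projection of the
    matrix onto a low-dimensional subspace. Descriptors can be extracted at
    multiple Gaussian scales and from subwindows of the matrix, and the
    resulting per-panel SVM scores are fused by score-normalized weighted
    sum rules. A synthetic-texture generator provides labeled datasets with
    controllable spatial correlation so the full pipeline is testable
    offline, and a small command-line interface exposes extract/evaluate
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
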