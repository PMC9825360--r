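Package: lcmil
Title: Refining Coarse Annotations on Single Slide Images with Label-Cleaning
    Multiple Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines coarse (inaccurate) region annotations on a single
    whole-slide image by treating patch labels induced by the annotation as a
    noisy-label problem. A multiple-instance-learning classifier (attention
    pooling or mean instance pooling) is trained with a focal loss on bags
    sampled from the noisily labeled patch pools, then every patch is re-scored
    as a singleton bag; the score map is thresholded with Otsu's method on the
    originally-positive patches and cleaned with morphology to produce a refined
    mask. Includes a synthetic two-texture slide generator with exact ground
    truth, the uniform-flip and omit-small-lesions annotation noise models,
    deep k-nearest-neighbour and rank-pruning baselines, and per-slide
    segmentation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    glmnet,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
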