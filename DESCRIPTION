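Package: milct
Title: Cross-Scale Transformer with Multiple-Instance Learning for Fundus
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dual-branch cross-scale vision transformer with an
    attention-based multiple-instance-learning head for binary
    classification of colour fundus photographs, targeted at detection of
    the enhanced arterial light reflex, an early fundus sign of systemic
    atherosclerosis.  The package provides the full preprocessing chain
    (border removal, contrast-limited adaptive histogram equalization,
    Gaussian background subtraction, minority-class balancing
    augmentation), the two-branch transformer backbone with multi-head
    cross-scale attention fusion, the attention-pooled bag-level
    classifier, a jointly weighted cross-entropy objective, cross-validated
    training and evaluation with standard classification metrics and ROC
    analysis, gradient-weighted class activation maps on the patch-token
    grid, and a deterministic synthetic fundus generator so every code path
    is exercisable without access to clinical data.  All network forward
    and backward passes are implemented in base matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    pROC,
    caret,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils-image.R'
    'preprocess.R'
    'nn-primitives.R'
    'backbone.R'
    'milhead.R'
    'model.R'
    'train.R'
    'metrics.R'
    'synth.R'
    'gradcam.R'
    'io.R'
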