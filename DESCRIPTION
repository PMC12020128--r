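Package: pestshift
Title: Continual Test-Time Adaptation for Multi-Task Pest Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pest detectors trained on clean imagery degrade when the deployment
    environment drifts (low light, fog, rain, snow, sensor noise). pestshift
    implements a cross-domain detection framework at desk scale: a learnable
    strong augmenter trained adversarially against a class-consistency
    classifier plus a stochastic weak augmenter; a dual-branch model pairing an
    object-detection main branch with an image-segmentation auxiliary branch,
    fused after every backbone stage by learnable sigmoid-gated GeLU message
    passing; and continual test-time adaptation that selects the
    highest-confidence prediction across photometric variants of each test
    image as a pseudo-label and updates both branches online. A synthetic-scene
    generator with parameterized weather corruptions, YOLO/COCO label I/O, and
    a detection/segmentation evaluation harness (precision, recall, mAP50,
    mAP50-95, confusion matrices, continual-domain reports) exercise the whole
    pipeline end-to-end. All differentiable components run on a small
    tape-based reverse-mode autodiff engine written in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
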