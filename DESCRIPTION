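Package: vesselfuse
Title: Foundation-Feature Fusion for 2D Cerebral Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid two-dimensional vessel segmentation for TOF-MRA brain
    slices. Implements an nnU-Net-style encoder-decoder backbone whose
    encoder features are fused with frozen foundation-encoder features
    through frequency-domain low-rank adapters (FrequencyLoRA) and a
    parallel channel-spatial attention gate, trained with a weighted
    focal + cross-entropy + Dice compound loss under case-level five-fold
    cross-validation. Includes a synthetic TOF-MRA slice generator, the
    full preprocessing chain (non-zero cropping, spline resampling,
    z-score normalization, augmentation), surface-distance evaluation
    metrics (Dice, IoU, HD95, ASD, precision/recall/F1) with brute-force
    oracles, and a training/inference/evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
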