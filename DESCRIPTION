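Package: strokevit
Title: Adapter-Tuned Vision Transformer Segmentation of Ischemic Stroke Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-based 2D segmentation of ischemic stroke lesions on
    non-contrast CT and diffusion-weighted MRI volumes. Implements a
    configurable vision-transformer encoder with residual bottleneck
    adapters inserted after selected transformer blocks, an
    attention-enhanced multi-scale upsampling decoder with deep
    supervision, hybrid Dice plus binary cross-entropy training with
    hierarchical learning rates, and a volumetric evaluation suite
    (Dice, IoU, Hausdorff distance and its 95th percentile, volumetric
    difference percentage, volumetric correlation). Includes a
    deterministic brain-phantom generator producing NIfTI volumes with
    exact lesion masks for desk-scale experiments, a NIfTI data
    pipeline with the training augmentation policy, and a thin
    command-line interface. The forward and backward passes of the
    network are implemented directly on matrix operations, so the
    package is self-contained and CPU-only.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
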