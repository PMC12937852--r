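---
title: "Methods: adapter-tuned transformer segmentation of stroke lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adapter-tuned transformer segmentation of stroke lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Acute ischemic stroke lesions are segmented slice by slice from 3D NCCT or
DWI volumes. On non-contrast CT the infarct is a subtle, low-contrast
density change; on diffusion-weighted MRI it is bright and sharply
delineated. `strokevit` implements a 2D slice-based segmentation network
with three parts:

1. **A vision-transformer encoder.** Each normalized slice (replicated to
   3 channels) is split into non-overlapping `patch_size` squares,
   flattened, linearly projected to `embed_dim`-dimensional tokens, and
   given learned positional embeddings. A class token and optionally a
   set of register tokens join the sequence. The tokens pass through
   `depth` pre-norm transformer blocks (multi-head self-attention,
   GELU feed-forward, layer norm, residual connections) and a final layer
   norm; the patch tokens are then reshaped row-major into a spatial grid
   of size `H/patch_size x W/patch_size`. The reference configuration is
   ViT-B/16: 16-pixel patches, 768 dimensions, 12 blocks, 12 heads,
   224x224 input, about 86 M encoder parameters.

2. **Residual bottleneck adapters.** After selected blocks (3, 6, 9 and
   12 in the reference configuration) every token is updated as
   `y = x + W_up GELU(W_down x + b_down) + b_up` with a 48-dimensional
   bottleneck. The four reference adapters add exactly 298,176 trainable
   parameters, below 0.35 % of the encoder. Two regimes exist: frozen
   backbone (only adapters and decoder train) and unfrozen (the backbone
   trains at a tenth of the adapter learning rate).

3. **An attention-enhanced multi-scale decoder.** The token grid is fused
   by four parallel convolution branches (1x1, 3x3, and 3x3 with dilation
   2 and 4, each to `branch_channels` = 192 channels), concatenated,
   refined by a 3x3 convolution and added back to the grid through a
   residual connection. Four upsampling stages each apply a 2x transpose
   convolution, batch norm, GELU, then a serial attention pair: channel
   attention `Mc = sigmoid(MLP(avgpool) + MLP(maxpool))` followed by
   spatial attention `Ms = sigmoid(conv7x7([mean; max]))`. Auxiliary 1x1
   classifiers on stages 1 and 2 provide deep supervision at 1/8 and 1/4
   resolution; the final head (3x3 convolution, batch norm, GELU, 1x1
   classifier, bilinear resize) emits full-resolution logits.

Training minimizes `L = L_Dice + L_BCE + 0.3 * sum_i L_aux,i`, where each
auxiliary term mirrors the main Dice+BCE term on bilinearly upsampled
auxiliary logits. Optimization uses Adam (beta1 0.9, beta2 0.999, weight
decay 1e-5), batch size 8, hierarchical learning rates (1e-5 backbone,
1e-4 adapters, 1e-4 decoder), 100 epochs, and halves all rates when the
validation loss fails to improve for 10 epochs. Evaluation reports Dice,
IoU, Hausdorff distance and its 95th percentile, volumetric difference
percentage, and the dataset-level Pearson correlation of predicted vs
true lesion volumes.

The whole network, its backward pass and the optimizer are implemented
directly on matrix operations (im2col convolutions, explicit attention,
hand-derived adjoints); the package has no deep-learning runtime
dependency and runs on a single CPU. Every layer's gradient is verified
against central finite differences in the test suite, and every numeric
kernel against loop-based brute-force oracles.

## Design choices where the architecture was open

* **Adapter placement.** Adapters are applied sequentially to a block's
  output tokens, after the second residual — the most common bottleneck
  adapter convention. Parallel insertion is not implemented.
* **Adapter initialization.** `W_down` is truncated-normal (sd 0.02);
  `W_up` and both biases start at zero, so each adapter is an exact
  identity at initialization and the pretrained (or random) encoder
  function is preserved at step 0. The 298,176 parameter count fixes the
  adapter to a plain down/GELU/up structure with no internal norm.
* **GELU.** The exact erf-based form, not the tanh approximation, so
  independent oracles reproduce activations to 1e-6.
* **Attention details.** Channel attention uses one shared two-layer MLP
  with ReLU between, hidden width `max(C/16, 8)` clamped to `[1, C]` —
  the CBAM convention. The serial order is channel first, then spatial.
  Disabling decoder attention (`use_attention = FALSE`) removes both
  modules, equivalent to unit attention maps.
* **Decoder widths.** Stage channels default to 256/128/64/32, tapering
  from the 768-channel grid while keeping the decoder lightweight. Batch
  norm + GELU follow each transpose and refine convolution. Auxiliary
  heads read the stage output *after* its attention pair, so deep
  supervision also trains the attention weights.
* **No encoder skips.** The encoder emits a single-scale grid; the
  decoder is hierarchical upsampling with attention, not a U-Net with
  encoder taps.
* **Auxiliary loss content.** Each auxiliary term includes both Dice and
  BCE, mirroring the main term. Auxiliary logits are upsampled to the
  target resolution rather than downsampling the mask, avoiding the
  ambiguity of binarizing a downsampled mask.
* **Dice accounting.** Dice is computed batch-globally (one ratio over
  all pixels in the batch) with smoothing constant 1.0, which keeps
  batches of lesion-free slices finite and stable.
* **Positional embeddings off-grid.** For inputs whose grid differs from
  the configured one, the learned positional grid is resampled
  bilinearly. A separable linear resampler has an exact adjoint, which
  keeps the embedding gradient simple; the reference input is fixed at
  224 so this only affects small test configurations.
* **Backbone initialization.** Truncated normal (sd 0.02) for all
  projections, zeros for biases — standard ViT practice. Loading
  externally pretrained encoder weights is available through
  `import_backbone_weights()` with an explicit name mapping; all tests
  use random initialization so the package builds and verifies offline.
* **Prediction restacking.** Per-slice probabilities are bilinearly
  resized back to the native slice shape and *then* thresholded at 0.5;
  resizing probabilities rather than masks gives smoother boundaries.
* **Scheduler monitor.** The plateau scheduler watches the validation
  loss; the best checkpoint is selected by validation Dice.

## Metric conventions

Hausdorff distances are computed literally over foreground voxel sets
(not extracted surfaces): covered interior voxels contribute zero
distance. Distances are scaled by per-axis voxel spacing from the NIfTI
header (unit spacing otherwise). The 95th percentile uses linear
interpolation between order statistics (`quantile` type 7). Degenerate
cases are defined, not crashed on: both masks empty gives Dice = IoU = 1
and HD = HD95 = 0; exactly one empty mask marks HD/HD95 undefined and
excludes the volume from those means; empty ground truth marks VDP
undefined; volumetric correlation requires at least two volumes and
nonzero variance. Whether published Hausdorff values are in millimetres
or voxels is often ambiguous; this package reports spacing units and
records the per-axis spacing alongside.

## The phantom generator

Desk-scale experiments run on synthetic brain phantoms rather than
clinical data. Each slice contains an elliptical brain (semi-axes about
0.42 and 0.36 of the edge, jittered 5 % per volume) with a smooth
plateau intensity near 0.5, a cosine rim roll-off, and low-frequency
cosine texture (amplitude 0.03). Lesions (0–3 per volume) are unions of
1–4 overlapping discs of radius 3–7 voxels, persist over a contiguous
slice interval, never extend outside the brain, and shift intensity by a
modality-dependent contrast: **+0.05** for NCCT-like volumes (near the
noise floor, as subtle as early infarcts on CT) and **+0.40** for
DWI-like volumes (bright and separable, like acute infarcts on DWI).
Gaussian noise (sd 0.02) is added last; the mask is the exact lesion
support; every volume is a pure function of `(seed, volume_index)`.

The generator exercises boundary metrics, attention and the training
loop with verifiable ground truth. It does **not** emulate anatomy
(ventricles, sulci, hemispheric symmetry), CT physics, partial-volume
effects, scanner artifacts, or the extreme lesion-size imbalance of
clinical cohorts — passing phantom tests therefore demonstrates that the
machinery is correct and can learn contrast-defined lesions, not that
clinical-level accuracy is reached. Clinical results additionally
require the external NCCT/DWI cohorts, pretrained encoder weights and
GPU-scale training.

## Desk-scale experiment sizes

The functional tests use problem sizes chosen so the full suite runs on
one CPU core:

* *Overfit check*: backbone depth 4, dim 64, patch 8 on 32x32 DWI-like
  slices; 8 lesion-bearing slices, at most 200 Adam steps at rate 1e-3
  for every group (a deliberately aggressive rate appropriate for a tiny
  randomly initialized model), expecting training Dice > 0.9 and Dice >
  0.8 on a held-out single-lesion phantom.
* *Freeze-regime comparison*: depth 2, dim 32, patch 8 on 24x24 slices;
  20 volumes (14 train / 6 validation, split by volume), 30 epochs, 3
  seeds. Rates keep the protocol's hierarchy (backbone one tenth of
  adapters/decoder: 1e-4 vs 1e-3). With a *random* backbone the frozen
  regime can only shape adapters and decoder around fixed random
  features, so mean best validation Dice of the unfrozen regime should
  be at least as high — the comparison is asserted as an ordering only.

## Known limitations

* Strictly 2D: no through-plane context; stacked predictions can be
  discontinuous across slices.
* CPU matrix-op implementation: reference-scale *training* is out of
  reach; reference-scale forward passes and all desk-scale training are
  practical.
* Batch norm statistics are computed over whatever batch is given;
  single-slice batches in training mode are legal but noisy.
* The NCCT intensity path assumes Hounsfield-calibrated inputs for the
  0–80 HU window; uncalibrated CT should use the percentile path.
* Surface-based Hausdorff variants are not implemented; the voxel-set
  definition is the one reported.
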