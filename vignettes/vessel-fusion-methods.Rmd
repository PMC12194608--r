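---
title: "Hybrid foundation-feature fusion for 2D vessel segmentation: models and methods"
author: "vesselfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid foundation-feature fusion for 2D vessel segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Time-of-flight MR angiography (TOF-MRA) renders flowing blood bright without
contrast agents; on an axial slice, cerebral arteries appear as small,
scattered, quasi-elliptical bright cross-sections that typically occupy well
under 5% of the pixels. Segmenting them is an extreme class-imbalance
problem: a model can reach very low pixel error while missing every small
perforating vessel. `vesselfuse` implements a hybrid strategy for this
regime: a self-configuring-style 2D encoder–decoder backbone whose encoder
features are enriched with features from a large frozen *foundation* image
encoder, fused through frequency-domain low-rank adapters and a dual
channel–spatial attention gate, and trained with a compound
focal + cross-entropy + Dice loss.

## The backbone

The backbone is a classic U-shaped fully convolutional network with eight
encoder stages at the default configuration. Stage E0 operates at full
resolution; every later stage opens with a stride-2, 3×3 convolution that
halves the spatial grid and doubles the channel count (capped at 512). Each
stage is a stack of two conv–dropout–norm–ReLU units (instance
normalization, dropout probability 0 — the dropout slot exists but is
inert, following common practice for this architecture family). With a
640×640 three-channel input the schedule lands exactly on the shape anchors
used throughout the package's tests: stage E3 produces `(B, 256, 80, 80)`
and the E7 bottleneck `(B, 512, 5, 5)` — 640 compressed by seven halvings
to 5. The decoder mirrors the encoder with 2×2 transposed convolutions
(channel-halving, resolution-doubling), concatenates the skip feature at
each level, and carries a 1×1 two-channel prediction head per decoder level
for deep supervision. We use two output channels with a softmax rather than
a single sigmoid channel so that the cross-entropy and focal terms read
directly as class probabilities.

Deep-supervision targets are nearest-neighbor-downsampled masks; per-level
losses are combined with weights that halve per coarser level and are
normalized to sum to one, the finest level weighted most. Whether the
compound loss should apply at every level or only at full resolution is not
fixed by the architecture; we apply it at every level, which is the
convention that makes the auxiliary heads train with the same objective
they are evaluated with.

## The fusion path

A frozen foundation encoder supplies a feature pyramid. Two shape contracts
are supported: a single-scale contract with one `(256, 64, 64)` map, fused
only into the E7 bottleneck, and a multi-scale contract with
`(256, 256, 256)`, `(256, 128, 128)` and `(256, 64, 64)` maps, of which the
last two fuse into E3 and E7. The earliest, highest-resolution map is
deliberately never fused: early fusion would inject high-frequency detail
and noise at full resolution for little benefit. Because reimplementing a
pretrained ViT- or Hiera-based encoder is out of scope here, the package
ships a *deterministic stub* that honors the shape contracts: it pools the
input image to each contract grid, derives three fixed content channels
(intensity, squared intensity, gradient magnitude) and projects them to the
contract channel count through a fixed seeded random matrix squashed by
tanh. The stub is content-dependent — fusion is not vacuous — but carries
no learned weights and is frozen by construction. Any real encoder can be
plugged in through `build_seg_model(foundation_encoder = ...)` as a
callable honoring the same contract.

Each fused stage applies, in order:

1. **Scale adaptation** — adaptive average pooling onto the stage grid
   (e.g. 128×128 → 80×80, 64×64 → 5×5), plus a learnable 1×1 convolution
   when the stage needs twice the contract's channels (256 → 512 at E7).
   The pooling operator is the only downsampling primitive used; it is
   linear, so its backward pass is the transposed operator.
2. **FrequencyLoRA** — the frequency adapter takes the per-channel 2D FFT,
   modulates only the amplitude spectrum as `A' = A + μ · MLP(A)` (phase
   untouched) and returns the real part of the inverse transform; the MLP
   is a 1×1 reduce–restore pair acting across channels per spatial
   frequency, with reduction factor 8. The LoRA adapter then adds a
   rank-4 bottleneck residual `x + Up(Down(x))` (1×1 projections, no
   biases, `2·C·r` parameters). The restoring MLP layer and `Up` are
   zero-initialized, so the whole module is the identity at initialization
   — fusion starts from a configuration that cannot hurt the backbone and
   learns to deviate. Defaults: reduction 8, μ = 0.2, rank 4.
3. **Concatenation and projection** — channel-wise concatenation with the
   backbone stage feature (2C channels) followed by a learnable 1×1
   projection back to C.
4. **AttentionGate** — parallel channel and spatial attention,
   `O = I · σ(Wc) · σ(Ws)`. The channel branch is global average pooling
   followed by a two-layer MLP with layer normalization between the layers;
   the spatial branch compresses channels 8-fold with a 1×1 convolution,
   extracts multi-scale context with parallel 3×3 and 7×7 convolutions
   (summed), and projects to a single logit map. The branch heads are
   zero-initialized, so the gate starts at a uniform factor of 1/4 — a pure
   rescaling that the following instance normalization absorbs. Kernel
   sizes and hidden widths in the spatial branch are our choice; the
   architecture fixes only "multi-scale convolutional structure".

The fused feature replaces the encoder stage output for both the skip
connection and the next encoder stage.

**A numerical note on the frequency adapter's backward pass.** The
amplitude path is differentiated exactly (through the FFT, the amplitude
extraction and the MLP); the phase factor is treated as fixed during the
backward pass. At initialization the module is the identity and its input
gradient is exact; as the MLP weights grow the neglected phase term
introduces a small controlled bias in the *input* gradient only — all
*parameter* gradients remain exact, which finite-difference tests verify to
~1e-10. We accept this bias because the dominant gradient path (the
identity residual) is exact and the adapter's parameters, which do the
learning, see exact gradients.

## The loss

With per-pixel foreground probability $p_i$ and label $y_i$:

- cross-entropy $L_{CE} = -\frac{1}{N}\sum_i \log p_{i,y_i}$;
- focal loss $L_{Focal} = -\frac{1}{N}\sum_i \alpha_t (1-p_t)^\gamma \log p_t$,
  with $p_t = p_i$ for vessel pixels and $1-p_i$ for background, class
  weights $[\alpha_{bg}, \alpha_{fg}] = [0.25, 0.75]$ and $\gamma = 2$;
- soft Dice loss $L_{Dice} = 1 - \frac{2\sum_i y_i p_i}{\sum_i y_i + \sum_i p_i}$
  on the foreground probability, computed per image and averaged;
- the compound loss
  $L = \lambda_1(\alpha L_{CE} + \beta L_{Focal}) + \lambda_2 L_{Dice}$
  with $\alpha = \beta = 0.5$ and $\lambda_1 = \lambda_2 = 1$.

Numerical guards: probabilities are clamped at $10^{-8}$ inside logarithms,
and the Dice ratio carries a $10^{-5}$ smoothing term in numerator and
denominator so that an empty prediction of an empty mask scores a loss of
zero (it is correct) rather than being undefined.

## Preprocessing and augmentation

The preprocessing chain is: crop to the tight bounding box of strictly
non-zero pixels (cropping precedes resampling); resample to a target pixel
spacing — dimensions scale by the spacing ratio, images via separable
natural cubic-spline interpolation, masks via nearest neighbor so the label
set survives; per-image z-score normalization over all pixels (population
standard deviation; constant images map to zeros). Training-time
augmentation applies, with configurable probabilities, random rotation
(±15° default), isotropic scaling (0.85–1.15), elastic deformation
(Gaussian-smoothed random displacement field) and mirror flips; image and
mask receive the identical spatial transform, with bilinear sampling for
the image and nearest neighbor for the mask. Pure mirror flips are
implemented as exact array reversals, so they are involutions and preserve
pixel counts exactly. The augmentation parameter values are configuration
defaults, not claims about any particular dataset.

## Training protocol

Training uses SGD with Nesterov momentum 0.99 and weight decay, under a
polynomial learning-rate schedule
$\mathrm{lr}(e) = \mathrm{lr}_0 (1 - e/E)^{0.9}$. The initial learning
rate (0.01) and weight decay (3e-5) follow the conventions of the backbone
family since no canonical values are fixed by the architecture itself; both
are exposed in `train_config()`. The reference epoch budget is 250; the
global seed default is 3407. Cross-validation is five-fold at the *case*
level: cases are shuffled once, dealt into folds differing in size by at
most one, and every slice inherits its case's fold — no slice of a
validation case can ever appear in training, eliminating within-patient
leakage. Inference ensembles the five fold models by averaging their
per-pixel foreground probabilities and thresholding at 0.5. Whole slices
(not patches) are the training unit, and validation runs once per epoch;
both choices are configuration-level decisions.

## Evaluation metrics

Per image: Dice and IoU (percent), pixel-level precision/recall/F1
(percent; F1 is numerically identical to Dice, which the tests assert to
1e-9), and the surface metrics HD95 and ASD in millimetres. Contours are
mask pixels with at least one 4-connected background neighbor (image
borders count as background); distances are Euclidean between pixel
centers, scaled by the isotropic spacing. ASD is the symmetric mean of
directed nearest-contour distances. For HD95 the literal "95th percentile
of a maximum of two suprema" formulation is not computable as written, so
the package defaults to the common community reading — the 95th percentile
(linear interpolation) of the *pooled* union of both directed distance
multisets, which is symmetric — and exposes
`convention = "max_of_directed_percentiles"` as the alternative. If
exactly one mask is empty the surface metrics are undefined: they are
reported as `NA` and excluded (with a count) from aggregation, while
overlap metrics remain defined (0, or 100 when both masks are empty).
Aggregation is macro: per-image values first, then unweighted mean and
sample standard deviation (n−1) across images. The fast distance path is
an exact Euclidean distance transform; an O(n²) all-pairs oracle ships in
the same function (`method = "bruteforce"`) and the test suite holds the
two to 1e-9 agreement.

## The synthetic-data generator

`generate_slice()` emulates what the method needs from a TOF-MRA axial
slice, and nothing more: a dark background (mean 0.12), bright
quasi-elliptical vessel cross-sections (mean 0.85, random eccentricity
0.5–1 and orientation, radii 2–12 px at the 640 px default), additive
Gaussian noise clipped to [0, 1], and a hard cap on the vessel-pixel
fraction (5% default) enforced on the actual mask pixel count — a
configuration whose minimum vessel count cannot fit under the cap is
rejected. Ellipses are drawn anti-aliased on a 2× supersampled grid; the
mask marks pixels with coverage ≥ 0.5. `generate_dataset()` organizes
slices into cases that share per-case appearance parameters (intensity and
vessel-size jitter drawn once per case), so the case-level CV machinery has
realistic within-case correlation to protect against. The generator does
not model MR physics, flow enhancement, Rician noise or 3D vascular
topology; consequently, passing tests demonstrate that the pipeline's
mechanics (shapes, losses, optimization, leakage control, metrics) are
correct and that the model can learn this class-imbalanced blob-detection
task — they say nothing about segmentation accuracy on clinical TOF-MRA.

## Problem sizes used by the tests and the acceptance script

The end-to-end learning check trains the multi-scale fusion variant on 40
synthetic cases × 4 slices at 128×128 with a five-stage backbone (base
width 2, cap 32), batch size 8, for 30 epochs, and requires validation
Dice ≥ 60% on the held-out fold; in our runs it reaches ≈ 97%. The base
width of 2 is the smallest schedule that keeps the stage structure
(doubling, cap, deep supervision) intact, which is what the check
exercises; widening it raises the accuracy margin but not the conclusions.
`scripts/acceptance.R` reruns exactly this computation from scratch —
generation, case-level split, training, ensemble-style prediction and
macro-averaged evaluation — and writes the measured validation metrics as
JSON. Shape-contract tests run the full default 640 px architecture once
in inference mode.

## Known limitations

- The stub encoder is a shape-contract stand-in, not a learned model; the
  fusion path's *value* on real data can only be assessed with a real
  pretrained encoder plugged in.
- The frequency adapter's input gradient neglects the phase term (see
  above).
- Training is single-threaded CPU R; the implementation is written for
  correctness and small-problem speed, not for GPU-scale throughput.
- Only isotropic pixel spacing is supported in the surface metrics, and
  only 2D slices throughout.
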