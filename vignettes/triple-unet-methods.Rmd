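---
title: "Triple U-Nets: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple U-Nets: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdunet)
```

## The model family

The package implements three binary-segmentation networks over a common
static-graph engine.

**T-Unet.** A 5-level encoder–decoder in which each resolution level
("node") holds three *convolution units*. A unit is two 3×3 dilated
convolutions with dilation rate 4−i for unit i (rates 3/2/1), each
convolution followed by ReLU, batch normalization and dropout. Units
within a node are densely connected: unit i concatenates the outputs of
units 1..i−1 with its node input. Reading unit i across the four encoder
nodes, the transition node and the four decoder nodes yields sub-network
i; the three sub-networks run in parallel at widths 16/32/64/128/256 per
level and are read out by 1×1 convolutions with sigmoids, fused by a
final 1×1 convolution into the output mask. Decoder unit i receives the
2×2 transposed-convolution upsampling of the same-index unit one level
below plus a skip from the matching encoder node.

**TMD-Unet.** T-Unet plus (i) a *multi-scale input pyramid*: the image is
2×2 max-pooled four times and each scale — including full resolution,
whose feature map is the stem `I0` — passes through its own 16-filter 3×3
convolution (+ ReLU + BN) before feeding the encoder node of matching
resolution; and (ii) *dense skips*: decoder unit i concatenates encoder
units 1..i instead of unit i alone.

**Unet baseline.** The conventional 5-level network (two 3×3 convs + BN
per level, filters 32..512, plain skip concatenation, 2×2 transposed-conv
upsampling, single sigmoid output), kept solely as a parameter-count
reference point.

## Calibrating the graph against the published parameter table

The family's printed description leaves several layer-level choices open
(where batch normalization sits, the transposed-convolution kernel and
bias, how the pyramid is wired, what the first node consumes), and its
connectivity formulas and its printed per-sub-network parameter table are
not mutually consistent: no reading of the formulas alone reproduces the
table. Because the table is the only machine-checkable ground truth, the
package treats it as the arbiter. An exhaustive search over layer
conventions shows the following graph reproduces **all seven reference
values exactly** (T-Unet 1.944/4.477/8.384 M, TMD-Unet 2.018/4.749/9.119
M, baseline 7.765 M):

* batch normalization after **every** convolution (trainable scale and
  shift, 2 parameters per channel);
* transposed convolutions 2×2, stride 2, **bias-free**; regular
  convolutions keep biases; all convolutions use size-preserving padding
  (dilated convolutions pad by the dilation rate);
* encoder nodes 2–5: the pooled same-index map of the previous node (and,
  in TMD-Unet, the pyramid feature) feeds **units 1 and 3 only**; unit 2
  consumes the intra-node features alone. This asymmetry is forced by the
  table — the formula-faithful alternative (all three units receive the
  pooled input) overshoots the output-2 counts by ~0.4 M in both
  variants while matching outputs 1 and 3;
* node 1: every unit receives the raw image, plus the 16-channel stem
  features in TMD-Unet; T-Unet has no stem;
* the pyramid pools the **raw image** (not the stem features) and each
  level owns a 16-filter conv + BN;
* reference channel counts: 3-channel input for the triple networks,
  1-channel for the baseline;
* the output-3 count includes the complete 55-parameter fusion head.

`graph_signature()` canonicalizes a built graph; the test suite uses it to
verify that disabling MSI and dense skips in a TMD-Unet configuration
reproduces the T-Unet graph node for node, and
`count_parameters()` is cross-checked against an independent analytic
count from recorded layer shapes.

## Losses and metrics

The hybrid loss is `dice + CE` with CE either plain binary cross-entropy
or the weighted form `-(1/N) Σ [(1−w)·y·log k + w·(1−y)·log(1−k)]`. The
weighted form is implemented exactly as written: although `w` is
nominally the foreground-class weight, it multiplies the *background*
term, and `w = 0.5` gives half the unweighted loss. We flag rather than
"fix" this, and default `w` to the training set's foreground pixel
fraction so the rarer class's error term is up-weighted under the formula
as printed. Predictions are clipped to `(1e-7, 1 − 1e-7)` before logs;
the dice smoothing constant defaults to 1 (the printed description states
its purpose, not its value).

Metrics come in two aggregations, both always computed: per-image means
of dice/mIoU (and of the rates), and rates from pooled pixel-level
confusion counts. On pooled counts F1 equals dice algebraically — the
fact that published evaluations report different DSC and F1 columns
implies a mixed aggregation basis, so reporting both is the only
reproducible policy. Binarization threshold 0.5; empty-truth vs
empty-prediction scores 1 (correct rejection); zero-denominator rates
yield 0 with a warning.

## Training harness

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) under
`lr = ilr · 0.9^(epoch/10)`. The exponent is real-valued (smooth decay),
which coincides with the integer-division reading at multiples of 10; a
flag switches to floor semantics. The schedule updates per epoch.
He-normal initialization; dropout active only in training mode; the loss
is applied to the fused output only by default (a `deep_supervision` flag
adds the three sub-output losses, averaged — not claimed to be the
original intent). Early stopping monitors validation loss with default
patience 10 and restores the best-validation weights.

Batch normalization during training uses per-sample spatial statistics
(the engine feeds images through the per-image graph one at a time,
accumulating gradients over the batch before each Adam step) and tracks
running moments (momentum 0.9, ε = 1e-3) for inference. For the batch
sizes used here (1–16) per-sample statistics are the stabler choice; it
leaves parameter counts untouched.

Augmentation draws one affine transform per sample — shear angle
U(−0.5, 0.5) radians, rotation U(−50°, 50°), per-axis zoom
U(0.8, 1.2), horizontal flip with probability ½, x/y shifts of up to 20%
of the side — applied identically to image and mask, with reflection
fill; masks are sampled nearest-neighbour and re-binarized. The shear
range is interpreted in radians (the dimensionless-shear convention; the
printed value 0.5 would be a no-op in degrees).

## Preprocessing operators

Sliding-window tiling uses 0-based, half-open windows; "64×128 overlap of
adjacent 128-px windows" is read as stride 64 on both axes, which
uniquely yields the published 1078/147/245 tile counts for the 512-px EM
splits (22/3/5 images × 49 tiles). Geometries that do not divide exactly
are rejected rather than padded — every published geometry divides.
Intensity windowing clips to `[low, high]` then maps affinely to [0, 1];
it is applied verbatim to MRI although Hounsfield units are CT-specific.
Center cropping puts the extra pixel of an odd margin on the trailing
side. Adjacent-slice stacking duplicates edge slices. Empty-slice
decimation keeps the first of every three consecutive foreground-free
slices (the published rule fixes the 2-of-3 exclusion ratio but not the
phase; keeping the first is the deterministic choice), never dropping a
foreground slice. "Cropped" for the atrium/spleen recipes is taken as
center crop.

## Synthetic data

`generate_blobs()` rasterizes unions of random ellipses exactly
(foreground 0.8, background 0.2, additive Gaussian noise, redrawn until
the foreground fraction lands in the requested range);
`generate_volume()` embeds a blob in a contiguous slice span. They
emulate the two properties the pipeline actually depends on —
foreground/background contrast and controllable class imbalance — and
deliberately none of the modality texture, anatomy, or artifacts of real
CT/MRI/endoscopy data. Tests passing on blobs therefore validate the
machinery (shapes, gradients, bookkeeping, convergence), not clinical
performance.

## Problem sizes in the test suite

The suite runs formula oracles on ~10²-pixel batches, structural checks
on full-width graphs (which cost nothing to build), and one stochastic
training check: a width-reduced TMD-Unet (base 4, filters 4..64) on eight
128-px single-channel blobs, batch size 1, initial learning rate 1e-3,
at most 60 epochs with an early exit once training DSC exceeds 0.97.
These sizes were chosen so a single CPU core finishes the whole loop in a
few minutes while still exercising every layer type end to end; the
full-width GPU-scale benchmark runs on the seven public datasets are
explicitly out of scope.

## Known limitations

* Binary segmentation only; no multi-class heads, no 3-D convolutions.
* The engine is single-image (no batched BN statistics) and single-core;
  it is built for correctness and desk-scale experiments, not throughput.
* Checkpoints are plain RDS of the model object.
* The encoder unit-2 connectivity follows the parameter table rather
  than the connectivity formulas (see the calibration section); users
  wanting the formula-faithful graph can obtain the symmetric wiring
  only by modifying the builder, which the package deliberately does not
  expose as an option to keep the reference counts authoritative.
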