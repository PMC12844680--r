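---
title: "Cross-modal crown delineation: model, data model, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal crown delineation: model, data model, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Individual tree crowns of a target species must be delineated, pixel by
pixel, from UAV imagery of mixed mountain forest. Two co-registered
sources are available per tile: a 3-band RGB image with high spatial
detail, and a 4-band multispectral (MS) image — Red (650 nm), NIR
(860 nm), Green (560 nm), RedEdge (730 nm) — that carries vegetation
physiological signal but less spatial detail. Neither source suffices
alone: crowns whose autumn coloring stands out in RGB may be spectrally
bland, while crowns that match the surrounding canopy in color can be
conspicuous in NIR/RedEdge reflectance; shadow darkens both. The
package implements a dual-branch fusion segmenter for exactly this
complementarity structure, together with the dataset-construction
pipeline, metrics, training engine, and a synthetic-scene generator
that reproduces the structure for controlled experiments.

## The model

**Dual-branch encoder (DBE).** Each modality passes through its own
ConvNeXt-style hierarchical backbone (4x4/stride-4 patchify stem;
stages of depthwise-7x7 + pointwise inverted-bottleneck blocks with
channel LayerNorm, GELU, and per-channel layer scale; 2x2/stride-2
downsampling between stages). The RGB branch exposes five levels,
feat1..feat5 at 1/2..1/32 resolution; feat1 comes from an auxiliary
stride-2 conv–norm–GELU block because the patchify stem's first output
is already at 1/4 — the decoder needs a 1/2-resolution skip, and this
keeps the stock backbone intact. The MS branch runs the same
architecture with a 4-channel stem but exposes only feat4 and feat5:
shallow MS features are treated as noise-prone and never consumed
downstream. When a pretrained 3-channel stem is available,
`extend_first_conv()` transfers it: visible-band filter slices are
copied verbatim and each extra band slice is drawn i.i.d. Gaussian
(sd 0.01).

**Cross-modal interactive fusion (CIF).** At feat4 and feat5 a
bidirectional cross-attention block (CotSR) lets each branch attend
over the other: with 1x1-projected queries/keys/values and N = H·W
positions,

    Y1 = X1 + gamma1 · softmax(Q1 K2') V2
    Y2 = X2 + gamma2 · softmax(Q2 K1') V1

single-head, no temperature or sqrt(d) scaling (the formulation prints
none, and the brute-force oracle in the tests pins this exact layout).
Query/key width is C/8 (the convention of the spatial-attention design
this block derives from); values keep full width. The gains start at 0
so the block begins as the identity. The enhanced maps are then
combined elementwise as `alpha·Y1 + beta·Y2` with learnable scalars per
stage, initialized at 1 — no channel expansion. The learned
alpha/beta per stage are an interpretable readout of how much each
modality contributes, and `fusion_weights()` reports them.

**Attention-enhanced decoder (AED).** Four Up-Concat stages rebuild
resolution: 2x bilinear upsample + 3x3 conv (a transposed-conv variant
is available), concatenation with the skip (upsampled-deep channels
first), CBAM recalibration, then a double conv–LayerNorm–GELU block.
Skips come, in order, from fused feat4 and the RGB branch's feat3,
feat2, feat1. A final 2x upsample and 1x1 head give two-class logits;
softmax is applied only at prediction time, and argmax ties break
toward background (conservative detection). CBAM computes channel
weights `sigmoid(MLP(avgpool) + MLP(maxpool))` with a shared
bottleneck MLP (reduction 16 by default, clamped to a divisor of the
concatenated width) and spatial weights from a 7x7 convolution over
the channel-wise mean and max planes. The channel-then-spatial order
is sequential, with the spatial map computed on the channel-refined
features; a `cbam_order = "parallel"` flag exposes the variant where
both maps are computed on the raw input, and `cbam_enabled = FALSE`
removes the module for ablations.

## Training recipe

Two-class pixelwise cross-entropy (no class weighting by default; an
optional weight vector exists for imbalance experiments), Adam with
beta1 = 0.9, beta2 = 0.999, weight decay 1e-4 applied to every
parameter (the framework-default convention the recipe implies), batch
size 4, learning rate cosine-annealed from 1e-4 to 1e-6 over 200
epochs, stepped per epoch. Early stopping monitors validation mean
IoU: "no improvement" means less than or equal to the best so far, and
`patience` consecutive non-improvements stop the run; the best-mIoU
checkpoint is always the one returned. A mixed-precision request flag
is accepted and recorded for config compatibility, but the CPU kernels
compute in double precision throughout, so it does not change
numerics. `train_steps()` provides a constant-rate, step-capped loop
for overfit fixtures and ablation studies, including the
`ms_noise = TRUE` condition that replaces the MS batch with fresh
uniform noise at every step.

## Data pipeline

Orthomosaics are tiled by a sliding window (640 px, 25% overlap, i.e.
stride 480); start positions run 0, stride, 2·stride, ... and a final
window is clamped to the image edge per axis so no pixel is lost —
the edge rule is ours, the source being silent. Polygon annotations
(LabelMe JSON) are rasterized by pixel-center even-odd testing with
centers at (j + 0.5, i + 0.5); overlapping polygons union. Screening
keeps tiles whose positive fraction strictly exceeds a threshold
(default 0 — at least one crown pixel), a reproducible proxy for
manual "discernible crown" screening. Augmentation (90-degree
rotations, flips, scale-then-center-crop, random crop-then-resize)
applies one geometric map jointly to RGB, MS and mask — bilinear for
imagery, nearest-neighbour for masks so they stay binary; free-angle
rotation is deliberately excluded to avoid border-fill ambiguity. The
train/validation split shuffles deterministically by seed and assigns
round-half-up of `train_frac·n` ids to training. An 8:2 split of 2665
ids gives 2132/533; published counts from a comparable corpus
(2073/592) are not an exact 8:2 partition, so the stated ratio, not
the counts, is what the implementation follows.

## The synthetic-scene generator

`generate_sample()` renders co-registered RGB + MS tiles with exact
ground truth. Target crowns are superellipses (exponent in
[1.6, 2.0], axis ratio in [0.6, 1.0], random rotation), placed by
bounded rejection sampling that limits overlap, so the rendered union
area stays provably within [0.5, 1] of the summed ellipse areas — a
countable geometry for the tests. Reflectance is flat per class plus
smooth multiplicative texture:

* **ms-cued crowns** keep the background-canopy RGB appearance
  verbatim and differ only in elevated NIR/RedEdge (0.70/0.45 against
  a 0.42/0.24 background);
* **rgb-cued crowns** are autumn-yellow in RGB and spectrally silent;
* **distractor canopies** are RGB-visible, spectrally silent
  non-targets.

Each crown is ms-cued independently with probability `frac_ms_cued`,
so the fraction holds in expectation even for single-crown tiles.
Shadows multiply all seven bands by a uniform factor in (0.3, 0.7)
over a blob or half-plane region near affected crowns. MS bands are
Gaussian-blurred then noised at the same pixel grid — the lower native
MS resolution is emulated photometrically, since real patches arrive
co-registered at equal size. This construction makes each modality's
failure set irreducible: RGB carries no evidence at ms-cued crowns,
the spectral bands none at rgb-cued crowns or distractors; only a
model that uses both can recover every target. What the generator does
**not** emulate: BRDF and sun geometry, registration error, mosaic
seams, continuous vegetation gradients, phenological variation.
Passing tests on these scenes therefore demonstrate that the
architecture can learn and exploit cross-modal complementarity — not
field-ready accuracy on real forests.

## Numerical and design choices

* **Initialization.** Convolution weights use fan-in-scaled (He)
  Gaussian init. The 0.02-sd convention of very deep pretrained
  backbones leaves desk-scale from-scratch models stuck at the
  base-rate constant prediction for hundreds of steps; fan-in scaling
  removes that plateau. Layer scale starts at 1e-6, attention gains at
  0, fusion weights at 1, biases at 0.
* **LayerNorm** is channelwise per position, eps 1e-6.
* **Channel attention** requires the width divisible by the reduction;
  the decoder builder clamps the requested reduction to the largest
  divisor of each stage's concatenated width.
* **Max-pool ties** route gradient to the first maximal element.
* **Bilinear resampling** uses half-pixel-center alignment; its
  backward is the exact adjoint (verified by inner-product identity).
* **Schedule** endpoints are exact: 1e-4 at epoch 0, 1e-6 at the
  final epoch, midpoint 5.05e-5.
* **Degenerate metrics** (zero denominators) return flagged `NA`,
  never a silent 0; dataset aggregation is micro (pooled pixel counts)
  with per-tile and macro summaries alongside.

## Desk-scale regimes and what the experiments showed

All learning tests run reduced models on one CPU: width multiplier
0.25 (overfit study: eight 128-px tiles, batch 4, constant 1e-3, at
most 300 steps) or 0.125 (modality studies: 64-px tiles, 32 training /
16 validation). Stage depths are (1, 1, 2, 1) at these scales.

One dynamic deserves record. With randomly initialized encoders and
Adam at 1e-3, the fused model's decoder learns within tens of steps to
rely on the RGB skip connections and suppresses its deep inputs — the
only path by which MS information arrives — before the MS encoder has
organized, and the output's sensitivity to the MS input does not
recover. Pretrained encoders (the full-scale recipe) sidestep this by
making deep features useful from the first step. At desk scale the regime that exercises the fusion mechanism is
a gentler constant rate (3e-4) and the narrower model, trained to
stabilization (600–800 steps, with best-validation-checkpoint
selection in the reproduction script);
there the fused model's held-out crown IoU clearly exceeds both
single-modality variants, the margin the architecture exists to
deliver. The noise-ablation study (fresh uniform noise replacing the
MS batch each step) shows the complementary behaviour: the learned MS
weight beta falls below its initial value at both fusion stages while
alpha does not, matching the interpretation of the learned dynamic
weights as modality-reliability gauges.

## Limitations

* The fusion weights are global scalars per stage; spatially or
  channel-wise adaptive weighting is out of scope.
* Tile-level inference only; stitching predictions back into an
  orthomosaic is not provided.
* No geometric/radiometric correction or cross-modal registration:
  inputs are assumed co-registered.
* CPU double-precision kernels: faithful and testable, but not a
  performance substitute for GPU training at full scale.
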