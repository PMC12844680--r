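# dcaunet

Pixel-level delineation of individual tree crowns from paired UAV
imagery: a 3-band RGB tile plus a co-registered 4-band multispectral
tile (Red 650 nm, NIR 860 nm, Green 560 nm, RedEdge 730 nm). The
package is built for the situation where neither source suffices
alone — some crowns stand out only by visible color and texture,
others only by their NIR/RedEdge reflectance, and shadow degrades
both — so the model must *fuse* the modalities rather than pick one.

## The model

A dual-branch cross-modal attention U-Net:

* **Dual-branch encoder** — two independent ConvNeXt-style hierarchies.
  The RGB branch emits five feature levels (1/2 … 1/32 resolution);
  the multispectral branch emits only the two deepest (feat4, feat5),
  keeping its noise-prone shallow features out of the decoder. A
  pretrained 3-band stem can be extended to 4 bands by copying the
  visible-band filters and drawing the extra band's filters from
  N(0, 0.01²) (`extend_first_conv()`).
* **Cross-modal interactive fusion** — at feat4 and feat5, single-head
  bidirectional cross-attention over spatial positions,

  ```
  Y1 = X1 + γ1 · softmax(Q1 K2ᵀ) V2
  Y2 = X2 + γ2 · softmax(Q2 K1ᵀ) V1
  ```

  followed by learnable dynamic weighting `F = α·Y1 + β·Y2`. The
  trained α, β per stage are an interpretable readout of modality
  reliability (`fusion_weights()`).
* **Attention-enhanced decoder** — four Up-Concat stages (2× upsample,
  skip concatenation, CBAM channel-then-spatial recalibration, double
  convolution) consuming the fused deep features and the RGB branch's
  shallow skips, then a 1×1 two-class head at full resolution.

Everything trains end to end on CPU: all layers carry exact,
finite-difference-verified backward passes over Rcpp/Armadillo
kernels. The package also implements the surrounding workflow:
sliding-window tiling with 25 % overlap and edge clamping, LabelMe
polygon rasterization (pixel-center even-odd), crown screening,
training-only geometric augmentation, seeded 8:2 splitting, IoU / PA /
Precision / F1 / mIoU evaluation with micro pooling, an Adam + cosine
schedule + early-stopping training engine, and a synthetic-scene
generator that reproduces the modality-complementarity structure with
exact ground truth.

## Worked example

Generate a small co-registered dataset in which half the crowns are
visible only in the spectral bands, train the reduced-width fused
model, and evaluate held-out tiles:

```r
library(dcaunet)

spec <- scene_spec(64, 64, n_crowns = 2, crown_radius_range = c(10, 16),
                   frac_ms_cued = 0.5, n_distractors = 2)
train <- generate_dataset(spec, 64, seed = 301)$samples
val   <- generate_dataset(spec, 16, seed = 701)$samples

model <- build_model(model_config(width_multiplier = 0.125,
                                  depths = c(1, 1, 2, 1), seed = 1),
                     mode = "fused")
fit <- train_steps(model, train, steps = 600, lr = 3e-4, batch_size = 4,
                   seed = 1, eval_every = 0)
evaluate_dataset(fit$model, val)$pooled
#>       IoU        PA Precision    Recall        F1      mIoU
#>  76.37834  94.87457  88.87161  84.45568  86.60739  85.11738
```

Against single-modality variants trained identically
(`build_model(..., mode = "rgb")` and `mode = "ms"`), the same run
yields held-out crown IoU 46.8 (RGB only) and 46.5 (MS only): each
sees roughly half the crowns, the fused model recovers both kinds.
The learned fusion weights after training report how the model
balances the branches:

```r
fusion_weights(fit$model)
#>   stage     alpha     beta
#> 1 feat4 0.9749741 1.021750
#> 2 feat5 0.9690981 1.009017
```

Here the model leans slightly on the multispectral branch at both
fused stages (β > α) — on these scenes the spectral bands are what
disambiguates target crowns from the color-matched distractor
canopies.

A command-line workflow (`simulate`, `prepare`, `train`, `evaluate`,
`predict`) is available through `run_cli()` or the wrapper script in
`inst/cli/dcaunet.R`; see the package vignette for the model details,
the synthetic-scene design, and the numerical choices.

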