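# tissuegrid

Patch-level multitissue classification and tile-based tissue segmentation
for histopathology images, in R.

Automated tissue segmentation of H&E-stained whole-slide images (WSIs) is
usually done in two stages: a classifier labels small patches (e.g.
tumour epithelium, stroma, lymphocytes, necrosis, ...), and the patch
predictions are stitched back into a slide-level label map. The hard part is
the appearance statistics of tissue: large *intraclass* variability (the same
tissue type varies widely in colour and texture) combined with small
*interclass* variability (different types can look alike). `tissuegrid`
implements a classifier head designed for exactly this regime, the
surrounding segmentation pipeline, and a synthetic data generator that
reproduces those statistics so the whole system is testable on a laptop.

## The model

For an input feature vector `x ∈ R^n` (the flattened convolutional feature
map — global average pooling is deliberately removed), each output node of
the **factorized bilinear layer** computes

    y = b + wᵀx + xᵀFᵀFx,        F ∈ R^{k×n}

The second-order term couples every pair of features through the Gram matrix
`FᵀF` at cost `k·n` parameters per node; it is evaluated as `‖Fx‖²` in
`O(nk)`, and the package carries the explicit `O(n²k)` double-sum expansion
`b + Σᵢ wᵢxᵢ + Σᵢⱼ ⟨fᵢ,fⱼ⟩ xᵢxⱼ` as an independent test oracle.

The `m` bilinear outputs `f` then pass through a **soft attention gate**
with learnable weights `w`:

    eᵢ = wᵢ·fᵢ,   a = softmax(e),   rᵢ = aᵢ·fᵢ

which rescales each feature by its softmax attention weight (the scalar
attention-pooled feature `c = Σ aᵢfᵢ` equals `sum(r)` and is kept as a
reference operation). A dense softmax head produces class probabilities.
Training uses cross-entropy with Adam (lr 3e-4, weight decay 1e-4, β₁ 0.9,
batch 32), rotation/flip/colour-standardization augmentation, and a plateau
schedule that multiplies the learning rate by 0.1 when the training loss
stops improving for 30 epochs. Compact CPU-trainable backbones
(`tiny_cnn`, `small_cnn`) are built in; convolution kernels are compiled
(Rcpp/RcppArmadillo) and all gradients are analytic, verified against finite
differences in the test suite.

The segmentation stage thresholds a downsampled slide (Otsu on saturation by
default) into a tissue mask, enumerates 224×224 tiles at stride 128 over the
tissue, classifies each tile, accumulates tile probabilities over their
footprints (overlaps are averaged), and takes the per-pixel argmax.
Grad-CAM heatmaps explain individual patch predictions. Evaluation reports
per-class precision/recall/F1 and macro averages, where the reported
*average F1* is the harmonic mean of macro-precision and macro-recall.

## Worked example

```r
library(tissuegrid)

# six synthetic texture classes emulating multitissue patch statistics
pr <- synthetic_presets("easy")
ds <- generate_patch_dataset(pr$specs, n_per_class = 300, size = 32,
                             seed = 7, class_names = pr$class_names)
sp <- split_dataset(ds, 0.8, seed = 7)

cfg <- model_config(n_classes = 6, input_size = 32,
                    bilinear_m = 16, bilinear_k = 4)
fit <- train_classifier(build_classifier(cfg, seed = 7),
                        sp$train, sp$val, train_config(epochs = 15, seed = 7))
glance(fit)
#> # A tibble: 1 × 5
#>   epochs train_loss val_loss val_acc lr_drops
#>    <int>      <dbl>    <dbl>   <dbl>    <int>
#> 1     15     0.0526   0.0706   0.978        0

evaluate_model(fit$model, sp$val)
#> <tg_eval> accuracy 0.9778 | macro P 0.9804 R 0.9778 | average F1 0.9791
```

After 15 epochs the held-out accuracy on the six-class benchmark is 0.978
with no learning-rate drops (the loss was still improving).
`evaluate_model` prints the macro summary in the reporting convention
above: 97.8% of 360 held-out patches are assigned their true class, and the
average F1 (harmonic mean of macro-precision 0.9804 and macro-recall
0.9778) is 0.9791.

Segmenting a synthetic slide end to end with that model (tile size must
match the model input, here 32 px; for 224-px models the canonical setting
is `tile_size = 224, stride = 128`):

```r
lay <- mosaic_layout(c(1024, 1024), tibble::tibble(
  row0 = c(32, 32, 544), col0 = c(32, 512, 128),
  height = c(480, 480, 480), width = c(480, 480, 768),
  class_id = c(0L, 2L, 3L)))
mo   <- generate_mosaic_slide(lay, pr$specs, seed = 77)
mask <- compute_tissue_mask(mo$image, downsample = 32)
grid <- enumerate_tiles(mask, dim(mo$label_map), tile_size = 32, stride = 16)
grid
#> <tg_tile_grid> 3355 tiles of 32 px, stride 16, over 1024 x 1024 slide
seg  <- stitch_segmentation(grid, classify_tiles(fit$model, mo$image, grid))
seg
#> <tg_segmentation> 1024 x 1024, 86.1% covered, 5 classes present
ov   <- render_overlay(mo$image, seg, class_names = pr$class_names)
```

The stitched label map agrees with the mosaic's ground truth on 92.7% of
covered tissue pixels (boundary tiles mix classes; the acceptance checks
use an oracle classifier to validate the stitching machinery itself, which
reconstructs region interiors exactly).

A command-line front end (`exec/tissuegrid`) wraps the same functions:
`tissuegrid synth|mosaic|train|finetune|segment|gradcam|evaluate ...`.

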