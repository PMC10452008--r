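# ghostunet

A trainable encoder–decoder segmentation network for tumour segmentation in
hematoxylin-and-eosin (H&E) histopathology image patches, written in R.  The
package is aimed at computational-pathology researchers who want to study the
building blocks — ghost convolutions, switchable normalization, a
bottleneck-transformer stage, and a class-wise dice loss — on a desk-scale,
fully synthetic pipeline, with no dataset download and no GPU.

## The model

The network is a U-Net whose encoder is built from **residual ghost
bottlenecks with switchable normalization (RGS)** and ends in a **bottleneck
transformer (BoT)**:

* A **ghost block** produces `⌈out/ratio⌉` *intrinsic* feature maps with an
  ordinary (1×1 point-wise) convolution and expands them with a cheap 3×3
  grouped convolution — one filter bank per intrinsic map — using strictly
  fewer weights than a plain convolution
  (`k_p²·in·intrinsic + k_c²·intrinsic·(ratio−1)` vs `k²·in·out`).
* **Switchable normalization (SN)** standardizes with softmax-weighted
  mixtures of batch-wise, instance-wise and layer-wise statistics
  (separate weights for mean and variance), so the network stays stable at
  batch sizes 1–2 where plain batch normalization degrades.
* The encoder halves resolution four times: max-pool + 1 RGS block, then 2
  and 3 stacked RGS blocks, then a **BoT** block — an RGS bottleneck whose
  middle 3×3 convolution is replaced by multi-head self-attention
  (`softmax(qᵀk/√d_h + qᵀ(R_h+R_w)/√d_h) v`, 4 heads, 2-D relative-position
  embeddings) — followed by 2×2 average pooling.
* The decoder restores resolution with four units of transposed convolution →
  ReLU → skip concatenation → 1×1 convolution → ReLU.

Training minimizes the **class-wise dice loss (CDL)**

```
L = 1 − [ y_p · D_fg + (1 − y_p) · D_bg ],
D_fg = (2Σ y·p̂ + ε)/(Σy + Σp̂ + ε),   D_bg analogously on (1−y, 1−p̂)
```

where `y_p` is the image-level lesion label: on lesion-free patches the loss
scores the *background* dice, so every false-positive pixel is punished and
negative patches are driven to the all-zero mask — the failure mode of the
plain dice loss.

Evaluation implements DSC, Jaccard index, relative volume difference,
TPR/FPR/precision, pixel accuracy and rank-based ROC AUC, plus the test-set
aggregation that yields the six-column report (DSC, AUC, PA, JI, RVD,
Precision).

Because no deep-learning framework is assumed, the package carries its own
compact tape-based reverse-mode autodiff over `(H, W, C, N)` arrays with
compiled im2col/col2im convolution kernels; every operation is validated
against finite differences in the test suite.

## Worked example

```r
library(ghostunet)

# 1. synthetic H&E-like data: 64x64 patches, half of them lesion-bearing
sp    <- synth_params(size = 64, seed = 1)
train_set <- synthesize_dataset(sp, 8)
test_set  <- synthesize_dataset(sp, 6, offset = 8)

# 2. train the reduced cpu-small profile (reference optimizer settings:
#    SGD, lr 1e-2, weight decay 1e-4, momentum 0.9, batch 2)
cfg <- train_config(profile = "cpu-small", seed = 42, val_fraction = 0)
res <- train(cfg, train_set, max_steps = 300)
dataset_dsc(res$model, train_set)
#> [1] 0.9877752
negative_fp_fraction(res$model, train_set)   # FP mass on lesion-free patches
#> [1] 0

# 3. evaluate on held-out synthetic patches
evaluate_model(res$model, test_set)
#> Test set: 6 images (4 positive)
#>  DSC 0.9765 | AUC 1.0000 | PA 1.0000 | JI 0.9543 | RVD 0.0445 | Precision 1.0000
#>  pixel-level PA 0.9951
```

The training dice (0.988 over the lesion-bearing patches) shows the network
has learned its 8 training patches, and lesion-free patches are predicted
fully empty.  On unseen patches it localizes the blob lesions accurately
(DSC 0.98, perfect image-level classification at AUC/PA 1.0, mild
over-segmentation at RVD 0.04).  Numbers are exactly reproducible from the
seeds shown.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ghostunet.R", package = "ghostunet"))')
Rscript $CLI synth    --out data --n-train 16 --n-test 10 --size 64 --seed 1
Rscript $CLI train    --data data/train --out model.rds --profile cpu-small
Rscript $CLI evaluate --checkpoint model.rds --data data/test --json report.json
Rscript $CLI predict  --checkpoint model.rds --images data/test/images --out pred
Rscript $CLI score    --pred pred --truth data/test/masks --json score.json
```

## Package layout

* `R/autograd.R`, `R/tensor-ops.R`, `R/nn-ops.R`, `src/conv_ops.cpp` — the
  autodiff engine and differentiable layers.
* `R/blocks.R`, `R/network.R` — ghost block, SN, RGS/BoT bottlenecks, MHSA,
  and the full network with checkpointing.
* `R/losses.R`, `R/metrics.R` — class-wise dice loss and the evaluation
  suite.
* `R/data-synth.R` — dense cropping/stitching, 0/255 mask PNG I/O,
  augmentation, and the synthetic generator.
* `R/train.R`, `R/cli.R` — SGD training loop, prediction, evaluation and the
  CLI.
* `vignettes/methods.Rmd` — the model, its assumptions, parameter defaults
  and design decisions in detail.
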