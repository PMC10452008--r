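---
title: "Methods: a ghost-convolution U-Net with a bottleneck transformer for histopathology segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a ghost-convolution U-Net with a bottleneck transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumour segmentation in hematoxylin-and-eosin (H&E) stained whole-slide images
is done patch-wise: a gigapixel-scale tissue scan is densely cropped into
512×512 RGB patches, a network predicts a binary lesion mask per patch, and
patch predictions are stitched back to slide scale.  Two practical
difficulties shape the architecture implemented here.  First, plain
convolutional encoders see only local context, while lesion boundaries benefit
from long-range structure; the encoder therefore ends in a
bottleneck-transformer stage whose multi-head self-attention (MHSA) relates
every spatial position to every other.  Second, GPU memory limits force very
small batch sizes (two, often one) at 512² resolution, where batch
normalization becomes unreliable; the blocks here normalize with *switchable
normalization* (SN), a learned mixture of batch, instance and layer
statistics that stays well-behaved at batch size 1.

## Architecture

The network is an encoder–decoder U-Net.

* **Stem** — two 3×3 convolutions with batch normalization and ReLU at full
  resolution (the stem deliberately uses plain BN; the switchable variant
  lives in the residual blocks).
* **Four downsampling stages**, each halving resolution:
  a 3×3/stride-2 max pooling followed by one residual ghost bottleneck
  (stage 1); two and three stacked residual ghost bottlenecks whose first
  block is strided (stages 2–3); and a bottleneck-transformer block followed
  by 2×2 average pooling (stage 4).  Skip features are captured at full, 1/2,
  1/4 and 1/8 resolution; the bottleneck sits at 1/16.
* **Four decoder units**, each doubling resolution: transposed convolution
  (kernel 2, stride 2) → ReLU → concatenation of the matching skip → 1×1
  convolution → ReLU, closed by a 1×1 convolution to the two class channels.

### Ghost blocks

A ghost block generates `ceiling(out/ratio)` *intrinsic* maps with an
ordinary convolution (1×1 point-wise here; 3×3 in the strided middle
position) and derives the remaining maps from them with a *cheap* 3×3 grouped
convolution — one small filter bank per intrinsic map.  With the default
ratio 2 the block emits half intrinsic and half cheap maps and always uses
strictly fewer weights than the plain convolution with the same channel
counts (`n_parameters()` verifies the closed form
`k_p² · in · intrinsic + k_c² · intrinsic · (ratio − 1)` in the tests).

### Switchable normalization

Each normalizer keeps two 3-vectors of importance logits (one for the mean,
one for the variance).  Softmax weights mix the batch-wise, instance-wise and
layer-wise first and second moments; the mixture then standardizes the input,
followed by a per-channel affine scale and shift.  Logits start at zero — an
unbiased equal mixture.  Running batch statistics are tracked with momentum
0.1 and replace the batch-wise component at inference; instance and layer
statistics are always computed from the input.  Saturating the logits
reproduces each pure normalizer to 1e−5 (tested against a hand-rolled
three-way oracle, including batch size 1).

### Residual bottlenecks

Both block types follow the ResNet bottleneck wiring: 1×1 ghost reduction (to
`out/4` channels) → SN → ReLU → middle operator → SN → ReLU → 1×1 ghost
expansion → SN → residual sum → ReLU, with a strided 1×1 projection (plus SN)
on the shortcut whenever shape changes.  The middle operator is a 3×3 ghost
block (optionally strided) in the RGS bottleneck, and MHSA in the bottleneck
transformer.  We place ReLU after each normalization (post-activation); the
block diagrams this follows do not pin down the ordering in prose, so this is
a declared choice, made once.

### Multi-head self-attention

Queries, keys and values are 1×1 projections.  Content logits are
`qᵀk/√d_h`; with relative positions enabled, per-head height and width
embeddings `R_h`, `R_w` add a content–position term `qᵀ(R_h + R_w)/√d_h`
(the query is pre-scaled, so both terms share the √d_h scaling).  The
embeddings are sized to the feature-map resolution seen in training
(`input_size/8`); inputs of any other size are rejected rather than silently
interpolated.  Four heads are the default.  A final 1×1 projection mixes the
heads.  Attention rows are checked to sum to one, and the output is invariant
to a common shift of all logits.

## Loss

Training minimizes the class-wise dice loss.  With per-pixel foreground
probabilities p, binary truth y and image-level lesion label
y_p ∈ {0, 1}:

* positive patch (y_p = 1): `1 − (2Σyp + ε)/(Σy + Σp + ε)` — soft dice of
  the foreground;
* negative patch (y_p = 0): one minus the soft dice of the *background*, so
  any predicted foreground is penalized and training drives lesion-free
  patches toward the all-zero mask.  The plain dice loss, by contrast,
  receives essentially no penalty for false positives when the truth is
  empty.

The formula for this loss is sometimes typeset as a sum of per-pixel ratios,
which does not algebraically reduce to a dice coefficient; we implement the
aggregated class-wise dice (sums inside numerator and denominator), which is
what the formula's own description — per-class dice similarity coefficients —
computes, and keep the literal per-pixel expression available as
`cdl_literal()` for comparison.  ε defaults to 1e−6: small enough not to bias
the coefficient on 512² patches, large enough to keep every denominator (and
gradient) finite at all-zero/all-one predictions.

## Evaluation

Per mask pair: DSC, Jaccard index and relative volume difference, with the
conventions that an empty–empty pair scores DSC = JI = 1 (a correct negative
segmentation) and that RVD is excluded when the annotation is empty.
Image-level classification uses the predicted lesion-pixel fraction as the
score; an image is called positive when the fraction exceeds τ = 1e−3 (the
reference protocol reports image-level AUC and accuracy over a balanced
positive/negative test set without a stated decision rule, so a near-zero fraction
threshold is declared here).  AUC is the rank-based Mann–Whitney estimate
with midrank ties — identical to the trapezoidal ROC area.  Pixel accuracy is
reported at both image level (the headline, matching the classification
framing) and pixel level.

DSC and JI are *averaged over images with a non-empty annotation*.  On an
empty annotation the per-pair dice is all-or-nothing — a single stray pixel
flips it from 1 to 0 — so including lesion-free images would make the average
a step function of essentially nothing.  The same convention is used for the
training-set dice (`dataset_dsc()`); the quality of negative-patch
predictions is instead measured by the continuous quantity the class-wise
loss actually optimizes there, the predicted foreground fraction
(`negative_fp_fraction()`, 0 for a perfect all-zero mask).

## Synthetic data

The generator emulates just enough of H&E appearance to exercise every code
path: an eosin-pink background and darker purple lesion blobs (unions of one
to four random ellipses, radii between size/16 and size/4), both textured
with a coarse block-noise field plus per-pixel Gaussian noise, quantized to
the 8-bit scale.  Half of the samples carry lesions.  Everything is
deterministic in `(seed, index)`.  What it does *not* emulate: nuclear
morphology, stain variation between labs, tissue folds, blurred boundaries
and annotation noise — so green tests here demonstrate that the machinery
(shapes, gradients, losses, metrics, I/O) is correct and trainable, not that
the network reaches clinical-grade accuracy on real slides.

## Training defaults and the desk-scale profile

The full profile defaults to the reference protocol: dense crop at stride
512, 512×512×3 patches, batch size 2, four attention heads, SGD with learning
rate 1e−2, weight decay 1e−4, momentum 0.9, 500 epochs, constant learning
rate (cosine decay is available behind a flag).
Channel widths default to stem 64 and stages
128/256/512/1024, the U-Net-family convention consistent with the
architecture's deepening ladder.  The `cpu-small` profile keeps every
optimizer setting and overrides only the widths (8; 16/32/64/128), the patch
size (64) and the epoch count, so the whole pipeline — synthesize, train,
predict, evaluate — runs in minutes on one CPU core.  Problem sizes used by
the test suite and the acceptance script (8 training patches, 300 optimizer
steps, a 10:10 balanced test set of 64×64 images) were chosen as the smallest
sizes at which training visibly converges and every metric is exercised;
the balanced test set mirrors, at reduced n, the balanced 54:54 design of the
reference protocol.

## Numerical and design choices

* **Autodiff.** No R deep-learning stack is assumed: the package carries a
  compact tape-based reverse-mode autodiff over `(H, W, C, N)` arrays, with
  compiled im2col/col2im kernels for convolution and pooling.  Every op is
  validated against central finite differences to ~1e−10 relative error.
* **Padding.** "Same" padding everywhere; only pooling and stride change
  resolution, which is what makes the ×2-per-stage bookkeeping exact.  The
  stage-1 "3×3 max pooling" is read as kernel 3, stride 2, padding 1 — the
  only reading that halves resolution exactly.
* **Transposed convolution.** Kernel 2, stride 2: each input pixel expands
  into a disjoint 2×2 block, eliminating overlap ambiguity and output
  cropping.
* **Initialization.** He-uniform convolutions, unit scales, zero shifts,
  zero SN logits (unbiased mixture), Gaussian position embeddings with
  sd = 1/√d_h.
* **Degenerate inputs.** Batch 0, channel mismatches, odd spatial dims under
  stride 2, indivisible input sizes and single-class AUC are rejected with
  messages naming both numbers; they are never silently padded or coerced.
* **Stitching.** Overlapping patch predictions are OR-combined
  (recall-preserving); probability averaging is available behind a flag.
  Whether slide-level predictions should be stitched or scored per patch is
  a settled question for slide-scale scoring, so both paths exist.
* **Training on negatives.** Both modes are exposed: training on positive
  patches only, or on both with negatives gated by the class-wise loss (the
  default).

## Known limitations

Pure-R autodiff keeps per-step cost acceptable only at reduced widths; the
full-width profile is functional but not practical to train here.  No
stain normalization, no pyramidal WSI formats (pre-exported tissue images are
assumed), no multi-class (>2) segmentation, no boundary losses or
object-level metrics, no pretrained weights.  The batch-wise running
statistics use the biased variance estimator; at the batch sizes targeted the
difference is negligible.
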