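---
title: "Methods: multi-scale pyramidal feature ensembles for cascaded OCT classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale pyramidal feature ensembles for cascaded OCT classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The diagnostic problem

Optical coherence tomography (OCT) B-scans are cross-sectional images of the
retina used to diagnose choroidal neovascularization (CNV), diabetic macular
edema (DME) and drusen against normal anatomy. Clinically the decision is
hierarchical: first "is this retina abnormal at all?", then "which disease
is it?". This package implements that hierarchy as a two-stage cascade —
a binary normal-vs-abnormal gate followed by a three-way disease subtype
head — alongside an all-at-once four-class head for comparison, on top of a
multi-scale convolutional feature pyramid.

## The architecture

The pipeline has four fitted or configured components.

**Scale adaptation (autoencoder).** Pretrained convolutional backbones
expect fixed input sizes, but clinical B-scans arrive at arbitrary sizes.
Instead of naive resizing, a small convolutional autoencoder maps an
arbitrary-size image to the three pyramid scales. Its encoder is
`encoder_stages` stages of 3×3 convolution + 2×2 max pooling with channel
doubling (`base_channels`, `2·base_channels`, ...). A linear 3-channel
projection of the encoder output is resampled bilinearly to the first
pyramid scale, giving the latent feature map `F_AE` (224×224×3 under the
default scales). `F_AE` is then processed by a 3×3 convolution, a stride-1
transposed convolution and a channel-expanding convolution to a 12-channel
map (224×224×12); the concatenation of `F_AE` and the processed map feeds
two heads: a high-resolution head producing the image actually consumed by
the pyramid, and a low-resolution head that reconstructs the input at its
original size and exists only to train the module.

The training loss combines robustness near and far from zero:

* pseudo-Huber `PH(x) = δ²(√(1+(x/δ)²) − 1)` — quadratic for small
  residuals, linear for large ones; `δ` (default 1, in units of pixel
  intensity on the [0, 1] scale) sets the crossover;
* log-cosh `log(cosh(x))` — twice differentiable everywhere, computed
  overflow-safely as `|x| − log 2 + log(1 + e^(−2|x|))`.

The combined objective is
`w_hi · [mean PH(high − target) + mean PH(F_AE − target)] + w_lo · mean logcosh(low − original)`
with weights `(1, 1)` by default. The number of pseudo-Huber terms and
their placement is a genuinely open design point; we apply both
high-resolution terms against the same target — an antialiased (area)
downsample of the original to the first scale — because a reconstruction
target must exist and both tensors live at that scale. The stride-1
transposed convolution is parameterized directly as a convolution, which it
equals algebraically at stride 1. Training is Adam on the full parameter
set; the returned model carries the parameters of the best epoch by
full-training-set loss, so the final loss never exceeds the initial one.

The 112 and 56 scales are derived from the high-resolution branch by 2×2
and 4×4 average pooling (bilinear resampling if the scale ratio is not an
integer): parameter-free, and preserving the module's learned content at
every scale.

**Dense backbone.** A densely connected feature extractor: 7×7/stride-2
stem convolution to `stem_channels`, 3×3/stride-2 max pooling, then
alternating dense blocks and transition layers, a final batch norm +
rectifier, and global average pooling. Within a block, layer *l* receives
the concatenation of the block input and all previous layers' outputs, so
its input channel count is `k0 + k(l−1)` with growth rate `k`; each layer
is BN → ReLU → 1×1 bottleneck (4k channels by convention) → BN → ReLU →
3×3 convolution emitting exactly `k` channels. Transitions are BN → ReLU →
1×1 convolution compressing channels by `compression` (floored, default
0.5 — required to make the reference configuration terminate at 1920) →
2×2 average pooling. The reference configuration is the DenseNet201
topology (k = 32, stem 64, blocks 6/12/48/32), whose terminal count is
1920; three fused scales give 5760. Every constructed backbone carries a
channel ledger computed purely from this arithmetic, and the forward pass
is audited against it layer by layer.

Batch normalization at inference uses stored running statistics
(ε = 10⁻⁵); freshly built backbones start from identity statistics
(mean 0, variance 1) and He-normal convolution weights under the config
seed. Pretrained parameters can be loaded from a checkpoint; the loader
validates every parameter's shape and names the first mismatch. All tests
run with seeded random weights — transfer learning is supported, not
required.

**Pyramid fusion.** One backbone per scale (independent seeded instances
by default; optionally shared), each producing a global-pooled feature
vector whose length is the terminal channel count regardless of input
spatial size. The fused predictor is the plain concatenation in scale
order. No per-scale standardization is applied at fusion: the concatenated
feature stays faithful to the per-path outputs, and classifiers that are
scale-sensitive (MLP, LR, SVM) standardize internally on their training
data instead.

**Cascade.** Stage 1 is a binary head on NORMAL vs everything else; its
abnormal score is gated at a configurable threshold (default 0.5). Gated
samples go to the stage-2 head over {CNV, DME, DRUSEN}. The partition is
exact by construction: a sample below threshold is NORMAL and can never
receive a disease label. Argmax ties break deterministically to the lowest
class index (CNV < DME < DRUSEN). Six classifier families are pluggable,
with the conventional defaults: SVM (RBF kernel, explicit one-vs-rest
ensemble), decision tree (gini, best splitter), random forest (gini, 100
trees), Gaussian naive Bayes (priors from data, variance smoothing 10⁻⁹
relative to the largest feature variance), L2 logistic regression (C = 1,
so ridge penalty λ = 1/n), and an MLP (two rectifier hidden layers 256/128,
40% dropout, Adam starting at 0.001 with reduce-on-plateau — factor 0.1,
patience 5 epochs, monitored on training loss — 50 epochs, batch 128).
The MLP defaults are sized for corpus-scale training sets; on small
fixtures, use more epochs and a smaller batch (the test suite's fixture
spec uses 150 epochs, batch 16).

## Evaluation

Binary metrics follow `Acc = (TN+TP)/(TN+TP+FN+FP)`, `Sen = TP/(TP+FN)`,
`Spc = TN/(TN+FP)`. Zero-denominator cells return `NA` — an explicit
undefined marker excluded from macro averages, never a silent 0. Multiclass
sensitivity and specificity are unweighted macro averages of the per-class
one-vs-rest values (the averaging scheme is not dictated by the
architecture; macro is the choice least sensitive to class imbalance).
AUC is the Mann-Whitney rank statistic with midranks for ties, macro
one-vs-rest averaged for multiclass. Cross-validation is stratified
(per-class fold counts within one), with every fitted component — the
autoencoder, classifier heads and feature standardizers — fit inside each
training fold only; the suite includes a leakage canary (a memorizing
classifier must collapse to chance on held-out folds). Method comparisons
use a two-sided paired Student's t-test on per-fold metrics, with a
degenerate-case marker when the fold differences have zero variance.

## The synthetic generator

Real OCT corpora are external and large, so the package ships a generator
that emulates the geometry that drives the diagnosis: a stack of smoothly
curved horizontal bands (retinal layers) of alternating reflectivity over a
dark background and a depth-fading choroid, with multiplicative uniform
speckle clipped to [0, 1]. Class morphology: DME carves a dark
intraretinal ellipse (cyst); CNV elevates the deep bright band into a
dome; DRUSEN puts small periodic bumps on that band; NORMAL is bands plus
speckle only. Defaults generate 256×320 images — deliberately unequal to
every pyramid scale so the "any size" path is always exercised. Generation
is a pure function of the spec (same seed, bit-identical pixels) and a
nearest-centroid baseline on mean row profiles verifiably exceeds chance,
so downstream accuracy tests are meaningful.

What the generator does **not** emulate: real speckle statistics
(multiplicative uniform is a texture stand-in, not a physical model),
vendor artifacts, shadowing, motion, mirror images, subretinal fluid
variants, or AMD subtypes. Passing tests therefore demonstrate that the
architecture is wired correctly and can learn class-discriminating
structure — not that it attains clinical accuracy on real data.

## Numerical choices and degenerate inputs

* Convolutions are im2col + GEMM (compiled); analytic gradients of the
  autoencoder are verified against central finite differences in the suite.
* Odd spatial sizes in pooling floor (the trailing row/column is dropped);
  transitions require at least 2×2 input and the stem at least 8×8.
* Resampling is separable bilinear (half-pixel centers) inside the network
  — its adjoint is used in backpropagation — and exact area averaging for
  reconstruction targets, which is antialiased under strong downsampling.
* All randomness (weight init, shuffling, fold assignment) flows from
  explicit integer seeds; training and inference are bit-reproducible.
* Division-by-zero metric cells return `NA` markers; degenerate paired
  t-tests are flagged rather than crashed.

## The cross-validated synthetic study

The end-to-end property checks run 5-fold stratified CV on 50 images per
class generated at 64×80, pyramid scales 56/28/14 (the same 4:2:1 ratio as
224/112/56), a 2-stage encoder with 8 base channels trained 2 epochs per
fold, a tiny backbone (k = 8, stem 16, blocks [2, 2], compression 0.5) and
logistic-regression heads. These sizes are the package's desk-scale study
conditions; they keep a full run to a few minutes on one CPU.

One architectural point generalizes beyond the study: the encoder depth
must not bottleneck the latent map below the first pyramid scale. With too
many pooling stages, `F_AE` is upsampled from a grid coarser than scale 1,
all three scales then carry the same smoothed content, and fusion merely
adds redundant noisy coordinates — single-scale features can beat the
fused ones. With the latent grid at or above scale 1's resolution, the
scales differ genuinely and the fused feature matches or beats every
single scale, which is the premise of pyramid fusion. Choose
`encoder_stages` so that `input_size / 2^stages` is not far below the
first target scale.

## Known limitations

* Clinical-grade accuracy requires training on the public OCT corpora
  (~10⁵ images) with pretrained backbones at GPU scale; the desk-scale
  synthetic study makes no such claim.
* The MLP head is a documented default (256/128 hidden units); published
  OCT classifiers of this family rarely disclose their head topology, so no
  equivalence of parameter counts is claimed.
* Backbones are feature extractors only: dense blocks are not trained
  end-to-end in R. Pretrained weights can be loaded from a checkpoint if
  converted to the package's format.
* SVM per-class scores are softmax-normalized one-vs-rest decision values —
  monotone in the decision function, not calibrated probabilities.
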