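# octpyramid

Cascaded classification of retinal OCT B-scans from multi-scale
convolutional feature pyramids, with a synthetic B-scan generator that makes
the entire pipeline testable on a laptop without any external data.

## Who this is for

Researchers in retinal image analysis who want a transparent, fully seeded R
implementation of a multi-stage OCT classification architecture — to study
its components (scale adaptation, dense feature pyramids, concatenation
fusion, cascaded decision-making), to benchmark classifier heads under
proper cross-validation, or to plug in their own images via the standard
folder-per-class layout (`root/{NORMAL,CNV,DME,DRUSEN}/*.png`).

## The architecture

1. **Scale adaptation.** A convolutional autoencoder accepts a B-scan of
   *any* size and emits the three pyramid scales (224×224×3, 112×112×3,
   56×56×3 by default). It is trained unsupervised with a combined robust
   reconstruction loss: two pseudo-Huber terms
   `PH(x) = δ²(√(1+(x/δ)²) − 1)` on the high-resolution side and one
   log-cosh term `log cosh(x)` on the reconstruction at the original size.
2. **Dense backbone per scale.** A densely connected feature extractor
   (growth-rate arithmetic `(FM)' = k0 + k(l−1)`, 1×1 bottlenecks,
   BN–ReLU–conv layers, compressing transitions, global average pooling).
   The reference configuration is the DenseNet201 topology: growth rate 32,
   64-channel stem, blocks 6/12/48/32, compression 0.5 — terminal feature
   length **1920** per scale, **5760** after fusing the three scales.
3. **Fusion.** Plain concatenation of the per-scale global-pooled vectors.
4. **Cascade.** Stage 1 gates NORMAL vs ABNORMAL; stage 2 separates
   CNV / DME / DRUSEN; an all-at-once four-class head is available for
   comparison. Six classifier families (MLP, LR, SVM, DT, RF, NB) with the
   conventional defaults are pluggable at every stage.
5. **Evaluation.** Stratified k-fold cross-validation with all fitting
   inside the training folds, confusion matrices,
   `Acc = (TN+TP)/(TN+TP+FN+FP)`, `Sen = TP/(TP+FN)`, `Spc = TN/(TN+FP)`
   (macro one-vs-rest for multiclass), Mann–Whitney AUC, and paired
   t-tests for method comparison.

A synthetic generator produces layered B-scan-like images with speckle and
class-specific lesions (CNV dome, DME cyst, drusen bumps), balanced per
class and bit-reproducible under a seed.

## Worked example

Five-fold cross-validated run of the full pipeline on synthetic data
(50 images per class at 64×80, pyramid scales 56/28/14, a small
2-stage autoencoder, a tiny dense backbone with growth rate 8 and blocks
[2, 2], logistic-regression heads):

```r
library(octpyramid)

ds  <- generate_dataset(synthetic_spec(50, image_height = 64,
                                       image_width = 80, seed = 11))
aec <- ae_config(target_scales = list(c(56L, 56L, 3L), c(28L, 28L, 3L),
                                      c(14L, 14L, 3L)),
                 encoder_stages = 2L, base_channels = 8L, epochs = 2L,
                 batch_size = 8L, seed = 21L)
bbc <- backbone_config(growth_rate = 8L, stem_channels = 16L,
                       block_layers = c(2L, 2L), compression = 0.5,
                       seed = 31L)
report <- run_pipeline_cv(ds, ae_cfg = aec,
                          pyramid_cfg = pyramid_config(bbc, aec$target_scales),
                          spec = classifier_spec("LR", seed = 41L),
                          k = 5L, seed = 51L)
print(report)
```

```
== cascaded (stage 1 + stage 2) four-class output ==
<oct_metrics_report> 5 folds (seed 51)
        acc    sen    spc
mean 0.6300 0.6300 0.8767
sd   0.1151 0.1151 0.0384
== stage 1: normal vs abnormal ==
<oct_metrics_report> 5 folds (seed 51)
        acc    sen    spc    auc
mean 0.7350 0.8267 0.4600 0.7287
sd   0.0487 0.0548 0.1673 0.0987
== all-at-once four-class ==
<oct_metrics_report> 5 folds (seed 51)
        acc    sen    spc    auc
mean 0.6300 0.6300 0.8767 0.8577
sd   0.0925 0.0925 0.0308 0.0701
== linear probes (accuracy) ==
<oct_metrics_report> 5 folds (seed 51)
      fused    X56   X28    X14
mean 0.6300 0.6450 0.555 0.4500
sd   0.0925 0.0873 0.057 0.0884
```

Reading the report: both the cascade and the all-at-once head reach 63%
four-class accuracy where chance is 25%, with the stage-1 abnormality gate
at 0.73 AUC and the four-class macro one-vs-rest AUC at 0.86. The linear
probes show the pyramid at work: the fused 96-feature predictor (0.630)
sits at the level of the best single scale (0.645 at scale 56, within the
fold-to-fold noise) while the coarser scales alone trail (0.555 and
0.450). These are desk-scale numbers from seeded *random* backbone weights
and a tiny synthetic corpus — they demonstrate that the pipeline learns,
not clinical performance.

For shell use, a thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "octpyramid.R", package = "octpyramid"))') \
  generate --n-per-class 10 --size 256x320 --seed 1 --out data/
```

with subcommands `generate`, `train-ae`, `emit-pyramid`, `extract`,
`train-cascade`, `predict` and `evaluate`.

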