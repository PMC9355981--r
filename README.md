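# paraseg

Automatic volumetric segmentation of the lumbar paraspinal muscles — left and
right **multifidus**, **erector spinae**, and **psoas major** — from axial
T2-weighted MRI, with a modified U-Net, a seven-metric accuracy suite, and a
reliability/statistics harness. Because clinical MRI cohorts of this kind are
not publicly distributable, the package ships a **synthetic lumbar phantom
generator** so that every stage — preprocessing, augmentation, training,
inference, evaluation, statistics — is runnable and testable end to end
without any external data.

It is aimed at musculoskeletal imaging researchers who want to train or
benchmark muscle-segmentation CNNs in R, and at methodologists who want a
fully reproducible, self-contained reference pipeline.

## What is inside

**Model.** A U-Net in 2D (per-slice) and 3D variants in which max-pooling is
replaced by stride-2 convolutions (stride 1 at the first level), upsampling
uses stride-2 transpose convolutions, skips concatenate encoder features into
the decoder, and every resolution level carries a residual stage:
two (3×3(×3) conv → instance norm → leaky ReLU) units whose input is added to
their output, with a 1×1 projection where channel counts differ. A final 1×1
convolution yields per-class scores for background + six muscles. The engine
(single-precision GEMM convolutions with hand-derived backpropagation and
AdamW) is implemented natively in Rcpp/RcppArmadillo — no external deep
learning framework is required.

**Training.** DiceCE loss — soft Dice over softmax probabilities plus
voxel-mean cross-entropy; foreground/background-balanced window sampling at a
positive/negative ratio of 1 (windows 256×256×1 in 2D, 256×256×32 in 3D at
full scale); AdamW with learning rate 10⁻³ and decoupled weight decay 10⁻⁴;
subject-level k-fold cross-validation; deterministic under a single seed.

**Evaluation.** For each muscle: Sørensen-Dice `2|SM∩GT|/(|SM|+|GT|)`,
Jaccard, conformity `1−(FP+FN)/TP`, true positive rate, true negative rate,
positive predictive value, volume ratio `SM/GT`, and absolute volumes in ml.

**Statistics.** ICC(2,1) (two-way random effects, absolute agreement, single
measure) with exact F-based confidence intervals, Bland–Altman limits of
agreement, balanced repeated-measures full-factorial ANOVA with
Mauchly/Greenhouse–Geisser sphericity diagnostics, Shapiro–Wilk /
skewness / kurtosis checks, and post-hoc paired t-tests.

**Augmentation.** Random affine (scaling −2.5–2.5 %, left–right mirroring
with anatomically correct label swapping, rotations ±2.5° per axis,
physically anchored translations of up to 25 in-plane / 2 through-plane
reference voxels) plus elastic deformation (smoothing σ 6–8 voxels,
magnitude 50–100, border padding), expanding a training set to a fixed
1000-image dataset.

## Worked example

Train a small 2D model on synthetic phantoms and evaluate it on a held-out
subject (a couple of minutes on one CPU):

```r
library(paraseg)

cohort <- lapply(1:6, function(i) generate_phantom(phantom_config(), i))

ck <- train_model(
  cohort[1:5],
  unet_config(dims = 2, channels = c(8, 16, 32), seed = 0),
  train_config(dims = 2, iterations = 1200, window = c(64, 64, 1),
               batch_size = 8, num_samples = 4, seed = 0))

pred <- predict_volume(ck, cohort[[6]]$image)
compute_metrics(pred, cohort[[6]]$mask)[, c("muscle", "dice", "volume_ratio")]
```

```
                muscle      dice volume_ratio
1      multifidus_left 0.8567708    0.8916256
2     multifidus_right 0.9090909    1.0344086
3  erector_spinae_left 0.9534180    1.0109489
4 erector_spinae_right 0.9732510    1.0124224
5           psoas_left 0.9400279    1.0603448
6          psoas_right 0.9424222    1.0363881
```

Each row is one muscle: `dice` is the spatial overlap with the reference mask
(1 = perfect) and `volume_ratio` the predicted-to-reference volume ratio
(1 = unbiased). The multifidus — the smallest muscle — is the hardest to
segment, as in clinical cohorts. Reliability of predicted volumes:

```r
m <- evaluate_cohort(ck, cohort[6])
icc_2_1(m$volume_sm_ml, m$volume_gt_ml)$icc
```

The full pipeline — phantom cohort → split → (augment) → train → predict →
metrics → statistics — is wired by `run_experiment()`; a thin command-line
wrapper with `phantom`, `augment`, `train`, `predict`, `evaluate`, `stats`,
and `experiment` subcommands is installed at `inst/cli/paraseg.R`.

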