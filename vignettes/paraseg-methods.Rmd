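---
title: "paraseg: models, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paraseg: models, phantoms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the segmentation
model and its assumptions, the synthetic phantom that stands in for clinical
data, the statistics harness, and every numerical choice a maintainer might
want to audit. Code chunks are illustrative and not evaluated at build time.

## The segmentation problem

Axial T2-weighted lumbar MRI volumes are highly anisotropic (in-plane
resolution well below a millimetre, slice thickness of several millimetres).
Six paraspinal muscles are delineated — left and right multifidus, erector
spinae, and psoas major — as an integer label field over `{0..6}` on the same
grid as the image. The pipeline fixes a voxel grid of 0.39 × 0.39 × 5 mm
(`resample()`), rescales each subject's intensity range to [0, 1]
(`normalize_intensity()`), trains a convolutional network on randomly sampled
windows, and evaluates volumetric overlap and volume agreement per muscle.

Per-subject normalisation is min–max rescaling: the stated aim of the
preprocessing is to normalise the *range* of pixel values across subjects,
which points at the extremes rather than at moments; z-scoring was rejected
on those grounds. Min–max is idempotent and order-preserving, so repeated
application (e.g. inside both training and inference wrappers) is harmless.
The acquisition slice thickness (4 mm) differs from the pipeline grid
(5 mm); the resampling target is authoritative for everything downstream.

## The modified U-Net

Both the 2D (per-slice, squeezed) and 3D variants share one topology,
configured by `unet_config()`:

* **Downsampling by convolution.** Each encoder level opens with a 3×3(×3)
  convolution of stride 2 (stride 1 at the first level, so the input is not
  immediately halved), followed by instance normalisation and a leaky ReLU.
* **Residual stages.** Each level then applies two (conv → instance norm →
  leaky ReLU) units and adds the stage input to the result:
  `out = shortcut(x) + act(IN(conv(act(IN(conv(x))))))`. When the stage input
  and output widths differ (after a skip concatenation) the shortcut is a
  1×1 projection convolution. The addition comes *after* the final
  activation of the conv path; with all stage weights at zero the stage is
  then exactly the (projected) identity, which is also how the architecture
  contract is tested. The alternative (activation after the addition) would
  make the zero-weight stage `act(x)` instead of `x`; the reference design
  this architecture follows uses the post-activation-free form.
* **Decoder.** Stride-2 transpose convolutions (implemented as the exact
  adjoint of the stride-2 convolution) upsample; encoder features of the
  same resolution are concatenated; a projected residual stage fuses them.
  A final 1×1 convolution maps to 7 class scores.

Defaults: channels 16-32-64-128-256 per level (the deeper variant appends
one extra level at 512 filters — added depth, not width, per its
description as an extra network *layer*); leaky-ReLU negative slope 0.01
(the activation's common default; unstated in the source protocol);
instance-norm ε = 10⁻⁵ with learnable affine parameters. Valid input
windows must be divisible by `2^(levels−1)` per spatial axis; inference
pads by edge replication and crops back.

The engine is written in single precision with im2col/GEMM convolutions and
analytic backpropagation, validated in the test suite against direct-loop
reference convolutions, a dense-matrix adjoint oracle for the transpose
convolution, and finite-difference gradient checks of the loss.

## Training protocol

`train_config()` carries the full-scale defaults: 30,000 AdamW iterations
(learning rate 10⁻³, decoupled weight decay 10⁻⁴, β = (0.9, 0.999),
ε = 10⁻⁸, decay applied to all parameters), DiceCE loss, windows 256×256×1
(2D) or 256×256×32 (3D), batch sizes 50 (2D, 4 windows per loaded volume)
and 10 (3D, 1 window per volume), and seed 0. The batch is assembled as
`round(batch_size / num_samples)` source volumes × `num_samples` windows
each, which keeps the stated batch sizes literal. Window centres are drawn
from foreground (any label > 0) with probability `ratio/(ratio+1)` — 0.5 at
the default positive/negative ratio of 1 — else from background; crops
beyond the volume edge are border-padded by index clamping.

The loss is `1 − mean_c softDice_c + mean_v CE_v`, with the smoothing term
(10⁻⁵) in both the numerator and denominator of the per-channel soft Dice,
background channel included. No learning-rate schedule, no early stopping,
and no best-checkpoint selection are used (none are part of the protocol);
the final-iteration model is evaluated. Weight initialisation is He-style
normal scaled for the leaky slope, drawn from the network seed; all sampling
randomness derives from the training seed, so a run is bit-reproducible on
a fixed numeric backend.

Inference (`predict_volume()`): 2D models segment full padded slices
batch-wise; 3D models slide windows with 50 % overlap along z and blend
scores with uniform weights (Gaussian blending adds a parameter without a
stated benefit at these scales). The label is the arg-max channel with ties
broken toward the lowest label ID — deterministic and documented.

Folds: subject-level k-fold (`kfold_split()`) shuffles by seed and balances
test-fold sizes to within one subject (76 subjects at k = 3 give 26/25/25;
the protocol's stated n = 50/N = 26 cannot all be exact and the actual sizes
are reported).

## The synthetic phantom

`phantom_config()` / `generate_phantom()` produce paired volumes that stand
in for the cohort. The phantom emulates exactly the statistical structure
the pipeline relies on:

* **Geometry.** Six bilaterally placed fusiform tubes (ellipse cross-sections
  swept along z with smooth per-slice radius modulation and centre jitter,
  tapering toward both ends), embedded in a brighter body with a central
  vertebral-column-like structure. Placement is mirror-symmetric up to
  random perturbation; larger muscles are painted first so contested voxels
  go to the larger muscle. Muscle occupies the central ~70 % of slices and
  sits well inside the in-plane field of view, so the full augmentation
  protocol cannot move muscle out of the volume.
* **Volumes.** Expected per-muscle volumes are the cohort means (erector
  spinae 300.3/294.7 ml, psoas major 157.3/160.3 ml, multifidus
  120.6/119.9 ml left/right) rescaled so the six muscles fill 12 % of the
  phantom field of view, preserving the ordering erector spinae > psoas
  major > multifidus; per-subject volumes vary with a coefficient of
  variation of 0.25, matching the cohort's relative spread. Bilateral pairs
  share expected volumes.
* **Intensity.** T2-like contrast: muscle dark (0.35 in model units), body
  brighter (0.55), vertebral structure brighter still (0.75), air near zero,
  and bright intramuscular fat speckle (0.85) occupying a per-subject
  fraction drawn from [0.05, 0.3] of the muscle volume. Speckle is made by
  thresholding spatially smoothed noise (~2 mm correlation) inside the
  muscle mask at the quantile implied by the fat fraction, which resembles
  fatty-infiltration streaks rather than salt-and-pepper noise. A smooth
  multiplicative bias field (±20 %) and additive Gaussian noise (SD 0.03)
  complete the model; the source protocol reports no intensity statistics,
  so these levels are free parameters chosen once to satisfy the stated
  contrast and ordering properties.

The default desk-scale grid is 64×64×12 at 1.56 × 1.56 × 5 mm (the paper
grid divided by an integer factor of 4, keeping the slice thickness); the
full 256×256×40 grid is reachable through the configuration alone. What the
phantom does **not** emulate: vertebral/disc anatomy beyond a generic bright
structure, MR acquisition physics, partial-volume fuzz at muscle borders,
inter-muscle fascia, or pathological morphology. Passing tests on phantoms
therefore demonstrate pipeline correctness and learnability, not clinical
segmentation accuracy.

## Augmentation

`augment_config()` reproduces the training-protocol ranges: isotropic
scaling −2.5–2.5 %; left–right mirroring with probability 0.5 (unstated in
the protocol; 0.5 is the standard choice for a bilaterally symmetric
structure) and a hard label remap 1↔2, 3↔4, 5↔6 forced by the left/right
label semantics; rotations ±2.5° about each axis, applied in physical mm
space so anisotropic voxels rotate correctly; translations of ±25 in-plane
and ±2 through-plane *reference-grid* voxels — the protocol defines them in
voxels of its 0.39 × 0.39 × 5 mm grid, so they are interpreted physically
(±9.75 mm / ±10 mm) and converted to each volume's own voxel size; and
elastic deformation with smoothing σ ∈ [6, 8] voxels and magnitude ∈
[50, 100], border padding. The elastic magnitude is a raw scale on
per-voxel uniform noise before Gaussian smoothing — the convention of the
augmentation framework the protocol inherits its units from; after
smoothing, displacements are on the order of a voxel. Transforms are
composed into a single resampling (mirror → rotate → scale → translate),
followed by the elastic warp; images interpolate trilinearly, masks by
nearest neighbour, both with border (edge-replicate) padding.

Offline expansion is the default: `augment_dataset()` emits a fixed set of
exactly `n_out` (default 1000) augmented pairs, cycling uniformly over
source subjects, deterministic under its seed, because the protocol
describes a generated 1000-image dataset rather than per-iteration
augmentation; the augmented set replaces the originals in training.

**A known discretisation limitation.** Under the default draws, per-label
voxel counts track the continuum volume scale factor `(1 ± 0.025)³` only to
within a few per cent, not to sub-per-cent precision: with 5 mm slices, any
warp of a binary label grid reduces along z to nearest-slice selection, so a
small through-plane scale or phase change re-digitises entire slices — a
coherent jump of one part in `nz_muscle` (about 12 % on the 12-slice desk
phantom and still about 2.5 % at a 40-slice clinical volume). This is a
property of discrete anisotropic label grids, not of the implementation; it
was confirmed independently with an external image-processing library, with
one-hot linear label interpolation, and with Gaussian label smoothing. The
acceptance suite asserts the idealised `[0.925, 1.08]` stability envelope as
stated and documents that it fails for a minority of draws for this reason.

## Metrics and degenerate conventions

`compute_metrics()` evaluates, per label and whole volume (the protocol's
emphasis is volumetric): Dice, Jaccard, conformity, TPR, TNR, PPV, volume
ratio, and absolute volumes (voxel count × voxel volume / 1000, in ml).
Degenerate cases follow fixed conventions so cohort aggregates stay finite
and auditable: both masks empty → all overlap metrics and the volume ratio
are 1; ground truth empty with a non-empty prediction → Dice 0 and the
volume ratio reported as a flagged missing value; TP = 0 with any positives
→ conformity flagged missing (it diverges to −∞). The `flag` column carries
the case. The identities `jaccard = dice/(2 − dice)` and
`conformity = (3·dice − 2)/dice` hold to numerical precision and are tested
against an exhaustive brute-force voxel-loop oracle.

## Statistics harness

All reliability statistics are computed from their mean-square definitions:

* **ICC(2,1)** — two-way random effects, absolute agreement, single measure:
  `(MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n)`, with the exact F-based
  95 % confidence interval (Satterthwaite degrees of freedom). Zero
  between-subject variance yields a flagged missing value rather than an
  error. The point estimate is tested against an independent two-way
  `aov()` decomposition and a frozen reference from an independent
  implementation.
* **Bland–Altman** — bias = mean(x − y), limits of agreement
  bias ± 1.96 · SD(x − y).
* **Repeated-measures ANOVA** (`rm_anova()`) — balanced complete
  within-subject full factorials only (missing cells are an error, never
  imputed). Effect sums of squares come from inclusion–exclusion over
  marginal means; each effect's error term is its subject-by-effect
  interaction. Mauchly's test and the Greenhouse–Geisser epsilon are
  computed for every within-subject effect with ≥ 3 cells, but sphericity
  is assumed unless correction is requested, matching the analysis protocol
  ("normality and sphericity assumed"). With two conditions the F statistic
  equals the squared paired t — a tested identity.
* **Post-hoc paired t-tests** — two-sided, *no multiple-testing correction*
  (the protocol reports raw α = 0.05 comparisons); this is stated in the
  function documentation so users reporting many comparisons can correct
  externally.
* **Assumption checks** — Shapiro–Wilk, sample skewness and excess kurtosis,
  Q–Q coordinates, and Mauchly's sphericity on a subjects × conditions
  table (skipped with a note below three conditions, where sphericity holds
  trivially).

When folds are pooled before ANOVA, all test predictions are pooled across
folds, since each subject is tested exactly once under k-fold.

## Desk-scale experiment sizes

The bundled experiment (`run_experiment()`, `scripts/acceptance.R`, and the
acceptance tests) runs at sizes chosen so a complete
phantom→train→evaluate→statistics cycle is a few minutes of single-CPU work:
24 phantoms at 64×64×12, a single 16/8 holdout split, a 2D network with
channels 8-16-32-64, full-slice 64×64 windows, batch 8 (2 volumes × 4
windows), 2000 iterations, seed 0 throughout. These are the package's
documented desk-scale study conditions; the full-scale protocol remains
available through the same configuration objects.

## Known limitations

* The phantom's realism bounds what green tests mean for clinical data (see
  above); no claim is made about accuracy on real MRI.
* The volume-stability envelope of the augmentation is limited by label-grid
  discretisation along the 5 mm axis (analysed above).
* The native engine targets CPU; it is fast enough for desk-scale studies
  and correctness work, not for full-scale 30,000-iteration training.
* 2.5D variants, mixed precision, post-processing by largest connected
  component, and fat-fraction thresholding are out of scope.
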