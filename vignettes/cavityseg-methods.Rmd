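---
title: "Methods: automated resection-cavity segmentation"
author: "cavityseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated resection-cavity segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After surgical resection of a glioblastoma, the radiation target (gross
tumor volume) is built around the resection cavity (RC): the fluid-filled
space left by the operation, which on MRI is liquor-isointense on T2w, dark
on T1w, and may contain air pockets (dark on every sequence) and blood
products (bright on T1w). Delineating the RC slice by slice is one of the
most time-consuming steps of radiotherapy planning and shows substantial
inter-expert variability. `cavityseg` implements a fully automated
segmentation pipeline for this structure from four co-registered,
skull-stripped MR sequences (T1w, T1w-gadolinium, T2w, FLAIR), together
with everything needed to train, cross-validate and evaluate it.

## Model

The segmenter is a two-dimensional, densely connected fully-convolutional
encoder–decoder in the DenseNet family. Its building blocks:

* **Dense unit**: batch normalization → ReLU → 3×3 convolution → dropout.
  Within a dense block each unit's output (the *growth rate* `g` in
  channels) is concatenated onto everything before it, so a block of `u`
  units adds `u·g` channels.
* **Encoder**: a stem convolution (+dropout) to 48 channels, then four
  levels of (dense block → transition-down). The transition-down is a
  channel-preserving dense unit followed by 2×2 max-pooling.
* **Bottleneck**: one dense block at the coarsest resolution.
* **Decoder**: per level, a transition-up (bilinear upsampling to the
  stored skip size, then a convolution compressing to `u·g` = 48 channels),
  concatenation with the skip connection, and a dense block.
* **Head**: a 1×1 convolution to two channels and a softmax giving
  per-pixel foreground/background probabilities.

With the defaults (`in_channels = 4`, `stem_channels = 48`,
`growth_rate = 12`, `units_per_block = 4`, `levels = 4`,
`dropout_p = 0.2`) the channel trace on a 200×200 input is
48 → 96 → 144 → 192 → 240 → 288 (bottleneck) → 336 → 288 → 240 → 192 → 2,
with resolutions 200 → 100 → 50 → 25 → 12 → … → 200. `channel_trace()`
prints the full table. Three reconstructions deserve a note, since the
published description pins the channel arithmetic but not every detail:

* the growth rate is 12 because each block of four units adds 48 channels;
* the transition-down convolution must map C→C *without* concatenation,
  otherwise the encoder counts 96, 144, … are unreachable;
* the transition-up must compress to exactly 48 channels, because each
  decoder output equals 48 (upsample) + skip + 48 (dense block), e.g.
  336 = 48 + 240 + 48. One printed decoder resolution (100×200) is
  internally inconsistent with the encoder symmetry and is treated as
  100×100.

Pooling uses floor semantics (25 → 12); upsampling always targets the
*stored* skip extent, so inputs need not be divisible by 2^levels — any
extent ≥ 2^levels per axis works and the output extent always equals the
input extent. The stem follows the table literally (convolution + dropout,
no normalization). Weights use rectifier-scaled (He) Gaussian
initialization from a seedable generator.

### 2.5D tri-planar inference

The 2D network is applied slice-wise along the three orthogonal
orientations (axial, coronal, sagittal), producing three foreground
probability volumes that are averaged voxel-wise (`fuse_triplanar()`) and
thresholded at 0.5 (`binarize()`; with two classes this equals argmax of
the averaged softmax output). The decision rule after averaging is not
fixed by the source description; thresholded probability averaging is the
default and a per-orientation binarize-then-vote variant is available via
`segment_study(fusion = "vote")`.

## Preprocessing and reference fusion

Inputs are assumed rigidly registered to the T1w-gadolinium grid and
skull-stripped upstream; the package verifies grid conformance (shape,
spacing, affine within 10⁻³ mm) and never resamples. Intensities are
z-score normalized to mean 0 / sd 1 **within the brain mask** (the union of
nonzero voxels across channels), per channel and per case; the zeroed
background would otherwise dominate the statistics. The population (n)
standard deviation is used so that renormalization is exactly idempotent.
Out-of-mask voxels are forced to 0 after normalization.

The reference segmentation is the per-voxel majority vote over the expert
masks: foreground when ⌊N/2⌋+1 or more raters agree (2 of 3). For even
rater counts a strict majority is required, so ties fall to background — a
conservative reference; `majority_vote(threshold =)` flips this. No
morphological post-processing is applied anywhere, matching the raw
reporting of segmentation errors in the source workflow.

## Training protocol

Training feeds batches of 16 slices of random orientation: each slice is
drawn by uniformly picking a case, an orientation, and a slice index whose
plane intersects the brain foreground (background-only slices carry no
gradient under plain cross-entropy). Batches mix cases; slices are kept at
native in-plane size and grouped by size within a batch. The loss is plain
pixel-wise cross-entropy, optimized by Adam with learning rate 10⁻⁴ and
standard moment parameters (β₁ = 0.9, β₂ = 0.999); no class weighting,
augmentation, or schedule. Stopping is a fixed epoch count
(`epochs × steps_per_epoch` optimization steps) — the full-scale protocol
is specified by wall-clock only, so the package makes the count explicit
configuration. All randomness (sampling, dropout, initialization) flows
from seeds; `derive_seed()` fans a single run seed out to the stages so
each stage is independently reproducible.

Cross-validation shuffles the case list once (seeded) and partitions it
into k test sets differing in size by at most one (30 cases, k = 6 →
25 train / 5 test). One fold is flagged for hyperparameter tuning,
mirroring the protocol of tuning on a single split only.

## Evaluation

`dice()` implements 2|A∩B|/(|A|+|B|); two empty masks score 1 (agreement
on emptiness — needed for degenerate phantoms) and empty-vs-nonempty
scores 0. `relative_volume_error()` is (V_auto − V_ref)/V_ref, negative
for underestimation; `volume_cm3()` converts voxel counts with the spacing
product. `evaluate_cohort()` scores every automatic-vs-rater,
rater-vs-rater, and automatic-vs-reference pairing and summarizes with
medians and linear-interpolation IQRs. `compare_groups()` reproduces the
statistical chain: Shapiro-Wilk normality per group, a Kruskal-Wallis
omnibus test (α = 0.05), and unpaired Wilcoxon rank-sum tests run **only**
when the omnibus test is significant. The tests themselves are the stock
`stats` implementations; the package contributes the gated workflow and
report shape. Degenerate all-constant input is reported as statistic 0,
p = 1, pairwise skipped. Both pooled and per-pairing groupings are exposed
(`cohort_stats()` groups by pairing label).

## The synthetic phantom cohort

The clinical cohort behind the original study is private, so the package
ships a generator whose output has the *structure* of the problem rather
than MR physics: an ellipsoidal brain with two ventricles (the classic
intensity confounder — CSF, like the cavity, is T2-bright and T1-dark), a
single cavity (ellipsoid with an optional smooth boundary perturbation)
whose reference label includes an air-pocket and a blood-product subregion,
per-tissue Gaussian intensities in arbitrary units, a low-order
multiplicative bias field (exp of a smooth random field — the signal
inhomogeneity failure mode), and additive noise inside the brain. Contrast
orderings are enforced by construction: cavity brighter than parenchyma on
T2w and darker on T1w, air darkest everywhere, blood brightest on T1w; the
cavity's FLAIR intensity sits between ventricle (suppressed) and
parenchyma, reflecting proteinaceous cavity fluid. The default grid is
64³ at 2 mm so that a full train-and-predict cycle runs on one CPU in
minutes; default cavity radii (14–20 mm) give volumes in the tens of cm³,
the clinical scale.

Simulated raters rethreshold the signed distance to the reference boundary
(6-connected chamfer approximation) after adding a smooth displacement
field, occasionally apply a global one-voxel erosion/dilation, and can be
told to exclude the air/blood subregions (an expert who does not count
them as cavity). The displacement sd default (1.6 mm) was fixed by a
calibration sweep over 20 seeds so that the median pairwise Dice of three
raters lands in the 0.80–0.90 band, emulating the mid-0.8 inter-expert
agreement reported clinically; per-seed values scatter around that band,
so checks aggregate over seeds.

What passing phantom tests does **not** show: robustness to real MR
artifacts, edema, infiltrating tumor borders, registration error, or
multi-scanner intensity variation. The phantom validates the machinery —
learnability, determinism, metric semantics — not clinical performance.

## Numerical and engineering choices

* Tensors are (H, W, batch, channels); the channels-last layout makes the
  (pixels × channels) matrix view zero-copy. Convolution im2col/col2im and
  the batch-norm column operations are implemented in C++
  (Rcpp/RcppArmadillo) after profiling showed the pure-R equivalents spend
  most of their time permuting and allocating arrays; all matrix products
  go through BLAS. The backward pass is verified against central-difference
  numerical gradients (relative error < 10⁻⁶) in the test suite, including
  odd spatial extents that exercise floor-pooling and skip-size restoration.
* Batch normalization uses batch statistics (population variance) in
  training and running statistics (momentum 0.1) in evaluation, ε = 10⁻⁵.
  Max-pool ties break deterministically in a fixed window order; evaluation
  mode contains no randomness, so inference is bit-reproducible.
* Label maps are validated to {0, 1} with a 10⁻³ rounding tolerance for
  float dialects; anything else errors, so interpolated masks cannot enter
  silently. Geometry comparisons use an absolute 10⁻³ mm tolerance.
* Reduced desk-scale configuration: the phantom experiments use
  `levels = 2` with narrower widths (`stem_channels = 12`,
  `growth_rate = 3`, `units_per_block = 2`) and learning rate 10⁻³ —
  hyperparameters chosen once for the reduced setting (the full-scale
  defaults keep the published values). Problem sizes used by the shipped
  experiments: a 6-case 64³ cohort with 3-fold cross-validation at 60
  optimization steps per fold, and a 2-case 32³ overfit fixture at 200
  steps; both chosen so the whole cycle runs in minutes on a single CPU.

## Limitations

The package assumes upstream rigid registration and skull-stripping
(conformance is checked, resampling is out of scope), segments a single
structure, and implements no surface-distance or dosimetric metrics. The
phantom generator is deliberately simple; transferring any conclusion to
clinical data requires clinical images.
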