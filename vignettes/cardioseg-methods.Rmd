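---
title: "cardioseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardioseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardioseg` detects and segments enlarged-heart regions in CT-like images
with a deliberately small pipeline: frozen convolutional features feeding a
three-member voting ensemble of classical classifiers. This vignette explains
the model, its assumptions, the tunable parameters, what the synthetic
phantom generator does and does not emulate, and the numerical and design
choices a maintainer would want to know about.

## The model

### Canonical image space

Everything operates on 224 × 224 × 3 images with intensities in [0, 1]
(`image224`). PNG/JPEG sources keep their native scale (8-bit 255 → 1.0);
DICOM sources have the rescale slope/intercept applied to the stored values
and are then min-max scaled per frame. No Hounsfield windowing is applied:
the classifiers only ever see relative local intensity, and a fixed window
would bake in scanner assumptions the rest of the pipeline does not need.
Images are resized bilinearly; label masks use nearest-neighbour so class
labels are never interpolated into non-classes. Grayscale input is
replicated across the three channels.

Masks (`label_mask`) carry fixed semantics: 0 = background (black),
1 = heart tissue (grey), 2 = enlarged region (white). On disk they use the
gray dialect {0, 128, 255} with a ±32 tolerance band; the codes are a
package convention, chosen to be maximally separated in 8-bit gray space.

### Frozen convolutional features

A filter bank of 64 kernels, each 3 × 3 × 3 (height × width × channel), maps
an image to a 224 × 224 × 64 feature map: stride 1, zero same-padding,
per-channel correlations summed, bias added, negatives rectified to zero.
"Convolution" follows the deep-learning convention (cross-correlation, no
kernel flip); for learned or randomly drawn kernels the two conventions are
related by a reflection and indistinguishable downstream.

The bank is frozen — never updated during training. Two provenances exist:

* `seeded_random` (default, seed 42): kernel entries ~ N(0, 1/fan-in) with
  fan-in 27, zero biases. A fixed random projection of each pixel's 3 × 3 × 3
  neighbourhood preserves local intensity information (the identity direction
  is almost surely in the span of 64 random projections of a 27-dimensional
  space), which is all the per-pixel members need. It also removes any
  network download from the test path.
* `pretrained_vgg_block1`: the 3 × 3 × 3 × 64 kernels + 64 biases of a
  VGG-style first convolutional layer, loaded from a local plain-text file
  (1728 kernel values in kernel-row/kernel-column/channel/filter order,
  then 64 biases). First-block features are edge/colour detectors; either
  provenance satisfies the pipeline's contract, and the choice is exposed
  in `pipeline_config()`.

The feature map is reindexed losslessly into the per-pixel table (row-major:
pixel (r, c) → row (r−1)·224 + c) and, for training, permuted into
frame-major order over non-overlapping 8 × 8 tiles (784 frames per image),
mirroring batch-wise frame extraction. Both reindexings are round-trip
tested.

### The ensemble

Each pixel row is classified by three members fitted on the same labeled
table:

* **Gaussian naive Bayes** (hand-written): per class and feature, mean and
  *population* standard deviation (divisor n); posteriors are computed in
  log space and normalized. Standard deviations are clamped at
  `sd_floor = 1e-6` so constant features degrade gracefully instead of
  producing infinite densities. A test compares the log-space path against
  a direct product-of-densities oracle.
* **Random forest** (backed by `ranger`): probability forest whose
  prediction is the average of the per-tree class responses, with
  `floor(log2(M)) + 1` candidate features per split (7 for M = 64) and
  bootstrap resampling. Single-threaded and seeded for bit-reproducibility.
* **Boosted trees** (backed by `xgboost`): additive trees minimizing the
  regularized logistic objective by its second-order expansion; each leaf's
  weight is the closed-form minimizer −G/(H + λ) of the per-leaf quadratic,
  with γ the per-leaf pruning penalty. Three classes use a softmax
  objective. A test verifies the leaf-weight closed form on a forced
  single-split geometry, and the recorded per-round training loss is
  asserted non-increasing.

Votes combine in one of three modes: **hard** (mode of member argmaxes),
**weighted** (argmax of weighted indicator sums), or **soft** (weighted
average of member probability rows), the default. Soft voting is the default
because all three members natively expose calibratable probabilities and the
averaged posterior also drives the ROC analysis. Ties always break to the
lowest class index in the ensemble's class order — a fixed, documented rule
rather than an RNG draw, so predictions stay deterministic.

Member weights default to uniform; no evidence favours one member a priori,
and the weights are config-exposed for users who have such evidence.

### From mask to diagnosis

The predicted three-class mask maps to a binary mask as the indicator of
class 2; 4-connected components smaller than `min_region_px = 25` pixels are
removed. At 224 × 224 scale, 25 pixels is well below any plausible enlarged
region (the phantoms' cores are thousands of pixels) but large enough to
absorb salt-and-pepper misclassifications, which is exactly the failure mode
of independent per-pixel decisions. A subject is diagnosed enlarged iff any
component survives. 4-connectivity is the conservative choice: it never
merges regions that touch only diagonally.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bank_seed` | 42 | RNG seed of the frozen random bank |
| `frame_size` | 8 px | training tile side; must divide 224 |
| `n_trees` | 50 | forest size K |
| `n_rounds` | 25 | boosting rounds |
| `learning_rate` | 0.3 | boosting shrinkage η |
| `lambda_reg` | 1 | L2 leaf penalty λ |
| `gamma_penalty` | 0 | per-leaf pruning penalty γ |
| `max_depth` | 6 | boosted tree depth |
| `sd_floor` | 1e-6 | NB standard-deviation clamp |
| `voting`, `weights` | soft, uniform | combiner mode and member weights |
| `augment` | TRUE | add horizontal+vertical flips of training pairs |
| `max_train_pixels` | 90 000 | class-balanced cap on training rows |
| `min_region_px` | 25 px | minimum surviving enlarged component |

Tree-member defaults are the libraries' conventional settings; the pixel cap
and tree counts are sized so a full 20-subject experiment trains in about a
minute on one CPU. Training draws up to `max_train_pixels`/3 rows per class,
*balanced* rather than proportional: the enlarged class is a small fraction
of all pixels, and balanced sampling keeps all members from defaulting to
the majority class. The resulting distortion of NB priors is irrelevant here
because the class-conditional likelihoods dominate on separable features.

## The phantom generator

Real cohorts of labeled cardiomegaly CT are small and not redistributable,
so the package ships a generator whose *statistical structure* matches such
a cohort: 20 subjects by default, 11 enlarged and 9 healthy. Each phantom is
a thorax ellipse (intensity 0.45) on dark background (0.10) containing a
heart ellipse (0.80) whose horizontal extent is `ctr` × the thorax extent —
the cardiothoracic ratio, the classical screening quantity. Subjects with
CTR ≥ 0.5 carry a brighter (0.95) concentric core labeled class 2; healthy
subjects have zero class-2 pixels. Default CTR ranges are 0.32–0.45
(healthy) and 0.55–0.70 (enlarged): comfortably inside the normal and
clearly-enlarged clinical bands, leaving the 0.45–0.55 borderline out of the
default conditions by design. Additive Gaussian intensity noise
(sd 0.02 ≈ 5 gray levels of 8-bit range) emulates mild acquisition noise.
Geometry (centre, thorax height) jitters deterministically per subject seed;
all per-subject seeds derive from one master seed, so a dataset is a pure
function of its spec.

What the phantoms deliberately do **not** emulate: anatomical texture, organ
context, partial-volume boundaries, scanner artifacts, or any ambiguity
between tissue and enlarged region — the three classes are separable from
local intensity by construction. Consequently the near-perfect accuracy and
Dice on phantoms validate the *plumbing* (features carry local intensity;
members fit and vote correctly; masks, components and diagnoses are computed
right), not clinical performance. On real CT the same pipeline would face
classes that are not locally separable, and nothing here measures that.

"Inversion in both horizontal and vertical orientations" is implemented as
two separate flips (original + h-flip + v-flip per pair), not a combined
180° rotation; the combined flip adds no new axis of variation for
left-right/top-bottom symmetry and was excluded. Augmentation applies to
training subjects only — augmenting evaluation data would average metrics
over copies of the same subject.

## Numerical choices and degenerate inputs

* NB posteriors: log-space accumulation with max-subtraction before
  exponentiation; underflow-free for 64 features.
* Constant features: `sd_floor` clamp (NB) and no-split trees (forest,
  boosting) — no errors.
* Dice with both masks empty is defined as 1.0: a healthy subject predicted
  healthy is a correct segmentation of "nothing". Macro Dice averages over
  classes present in *either* mask, so healthy subjects are not penalized
  for a class that neither truth nor prediction contains.
* Pixel-level sensitivity is undefined (NA) for subjects with no true
  class-2 pixels; summaries average over the subjects where it is defined.
* ROC thresholds sweep the unique scores with sentinels at both ends; ties
  group at one threshold, and the trapezoid AUC then equals the
  Mann–Whitney statistic with ties counted ½ (tested against the pairwise
  oracle).
* Degenerate DICOM frames (constant stored values) min-max to all zeros
  rather than dividing by zero; multi-frame files are rejected with an
  instruction to extract one frame.
* Hard/weighted vote ties, and soft-vote probability ties, break to the
  lowest class index — deterministic by construction.

## Problem sizes

The test suite and the acceptance script run the cohort experiment at 20
subjects (12 training, 8 held out) with flip augmentation (36 training
images, ~1.8 M labeled pixels before the 90 000-pixel balanced subsample)
and the default 50-tree/25-round members; this trains in roughly a minute
and evaluates 8 full-resolution masks (50 176 pixels each) in a few seconds
per subject. The bit-reproducibility check runs the complete pipeline twice
at a reduced size (8 subjects, 10 trees, 8 rounds, 30 000 pixels) and
compares masks, reports, and model archives byte for byte. These sizes are
the package's chosen study conditions, not limits of the method.

## Known limitations

* Per-pixel classification ignores spatial context beyond the 3 × 3
  receptive field; the component-size filter is the only spatial prior.
* The frozen bank is not tuned to the task; with non-separable real data a
  learned encoder would likely dominate.
* The DICOM reader covers uncompressed little-endian single-frame files
  only (the common export case); compressed syntaxes are rejected.
* Subject-level diagnosis reduces to "any surviving enlarged component";
  it does not estimate the CTR itself or grade severity.
* Member probabilities are not calibrated; soft voting treats them as
  comparable, which is an assumption, not a theorem.
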