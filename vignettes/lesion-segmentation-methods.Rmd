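---
title: "Methods: patch-focal losses, contrastive pretraining and lesion-wise evaluation"
author: "lesionseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-focal losses, contrastive pretraining and lesion-wise evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Detecting multiple brain metastases (BMs) on contrast-enhanced
T1-weighted (T1c) MRI is dominated by an extreme class imbalance: a
lesion under 3 mm across occupies a few dozen voxels in a multi-million
voxel volume. Voxel-wise training objectives see almost no signal from
such lesions — cross-entropy is overwhelmed by the background class,
and the Dice coefficient is numerically unstable for very small
overlaps — so small lesions are the ones automated systems miss, and
also the ones human readers miss. `lesionseg` implements, at a
configurable desk scale, the three ingredients of a training and
evaluation pipeline aimed at this regime:

1. a **patch-level focal loss** ("local region perceptron", LRP) that
   re-expresses lesion presence at the scale of small 3D patches;
2. **supervised contrastive pretraining** (CLP) of the encoder's latent
   tokens, pulling lesion tokens together and pushing them away from
   background tokens before the segmentation head is trained;
3. a **lesion-wise evaluation protocol** that scores detection per
   lesion (not per voxel), stratified by lesion size.

Because clinical MRI of this kind is not freely distributable, the
package ships a synthetic phantom generator that reproduces the
statistical shape of such a dataset and serves as the test bed for the
whole pipeline.

## The network

The segmentation model is a hybrid of a 3D U-Net and a small vision
transformer. A convolutional encoder (two `conv(3^3)` + instance-norm +
leaky-ReLU blocks per stage, then a strided convolution) downsamples the
input volume to a fixed `8 x 8 x 8` bottleneck grid. Each of the
`L = 512` grid cells is projected to a `d`-dimensional token; a
transformer (pre-norm blocks, multi-head self-attention, GELU MLP,
learned per-token positional embeddings) models global context over the
tokens. The decoder mirrors the encoder with transposed-convolution
upsampling and skip connections, ending in a two-class softmax
(background / lesion) per voxel.

Because the bottleneck is pinned at `8^3`, the per-stage downsampling
strides must multiply to `input_shape / 8`. Strides of 2 and 3 are
combined automatically (64 gives 2,2,2; 48 gives 2,3). This is the same
device nnU-Net uses to reach a target bottleneck from awkward shapes,
and it is what lets the package run its standard experiments on
`48^3` volumes.

Two architectural details matter for training at desk scale, and both
are standard practice in this family of models: activations in the
convolutional blocks are *leaky* ReLUs (slope 0.01), because with
Nesterov momentum 0.99 the effective step size is roughly 100x the
nominal learning rate and plain ReLUs die under the resulting early
updates, collapsing the decoder to a spatially constant output; and the
classification head's bias is initialized to the background prior
(foreground probability about 5%), so the cross-entropy term starts
near its optimum on the empty bulk and gradients concentrate on
lesions from the first step.

The network, its automatic differentiation tape, and the SGD/Nesterov
optimizer are implemented in the package itself (R with compiled
kernels for the 3D convolutions); every operator's vector-Jacobian
product is verified against central finite differences in the test
suite.

## The composite loss

Training stage 2 minimizes

$$
L \;=\; L_{\mathrm{Dice}} \;+\; (1-w)\,L_{\mathrm{CE}} \;+\; w\,L_{\mathrm{LRP}},
$$

where $L_{\mathrm{Dice}} = 1 - (2\sum p g + \epsilon)/(\sum p + \sum g + \epsilon)$
is the soft Dice loss with $\epsilon = 10^{-5}$, $L_{\mathrm{CE}}$ is
the voxel-mean cross-entropy, and $L_{\mathrm{LRP}}$ is a focal
classification loss over non-overlapping $8^3$-voxel patches. A patch
$l$ is labeled $y_l = 1$ iff it contains at least one lesion voxel; its
predicted presence probability $q_l$ is the maximum foreground
probability inside the patch. The focal term is

$$
L_{\mathrm{LRP}} = -\frac{1}{N}\sum_l\Big[\,y_l (1-q_l)^\gamma \log q_l
 \;+\; (1-y_l)\, q_l^\gamma \log (1-q_l)\Big],
$$

with focusing parameter $\gamma = 0.5$ and mixing weight $w = 0.4$ by
default.

Choices the formulation leaves open, and how this package resolves
them:

* **Patch aggregation.** "Presence in a patch" is not a mean quantity;
  the patch maximum expresses it directly and routes gradient to the
  strongest voxel. A noisy-OR alternative
  ($q_l = 1-\prod_v(1-p_v)$) is available via
  `loss_config(aggregate = "noisyor")`.
* **One-sided vs two-sided focal term.** A focal term containing only
  the positive-patch factor $y_l(1-q_l)^\gamma\log q_l$ cannot
  down-weight *negative* patches, because they contribute nothing at
  all; yet down-weighting easy negatives is the stated purpose of the
  focusing weight. The package therefore uses the standard two-sided
  binary focal loss by default and keeps the one-sided form behind
  `two_sided = FALSE`.
* **Normalization.** Patch terms are averaged (not summed) so the loss
  scale is comparable across volume sizes; cross-entropy is likewise a
  voxel mean.
* **Numerical safety.** Probabilities are clamped to
  $[10^{-7}, 1-10^{-7}]$ before any logarithm.

At $w = 0$ the composite reduces exactly to Dice + CE (the standard
nnU-Net objective), and it is affine in $w$; both facts are asserted in
the tests.

## Contrastive latent pretraining

Stage 1 trains the encoder and transformer only. The lesion mask is
subsampled onto the $8^3$ token grid by max-pooling (a cell is positive
iff it contains any lesion voxel — mean or nearest-neighbor subsampling
would erase exactly the small lesions the method cares about). With
token vectors $\tilde z_i$ (unit-normalized by default) and
similarities $s_{ij} = \tilde z_j^\top \tilde z_i$, every positive cell
$i$ acts as an anchor:

* attraction, summed over positive cells $j \neq i$:
  $-\log\!\big(e^{s_{ij}} / \sum_{j' \neq i} e^{s_{ij'}}\big)$, the
  denominator running over the *positives* only;
* repulsion, summed over negative cells $k$:
  $+\log\!\big(e^{s_{ik}} / \sum_{k'} e^{s_{ik'}}\big)$.

This is the literal triple-loop form of the supervised InfoNCE
objective; the implementation computes it with log-sum-exp
stabilization and is tested to equal the naive loops to $10^{-5}$ on
random latent fields. Two conventions are configurable because the
formulation admits both readings: the attraction denominator can
include the negatives (`denominator = "supcon"`, the standard
supervised-contrastive form), and tokens can be left unnormalized
(`normalize_tokens = FALSE`, with similarity clamping to prevent
overflow of the unscaled exponential).

Volumes whose token grid contains no positive cell contribute no loss
and are counted as skipped. Because the full pair loop over 512 tokens
is quadratic, training samples at most `max_anchors` anchors and
`max_negatives` negatives per step (seeded); the exact loop remains the
test oracle.

The effect of pretraining is measured by `separation_score()`: after
normalizing every latent dimension by the mean and SD of the non-lesion
tokens (so that nuisance scale differences are removed), the distance
between class centroids divided by the mean within-class RMS spread.
`tsne_embed()` exports a seeded 2D t-SNE embedding of the tokens for
visualization; the exact $O(n^2)$ algorithm is implemented in the
package since the token count is at most 512.

## Two-stage schedule

Both stages use stochastic gradient descent with Nesterov momentum
0.99 under a polynomial learning-rate schedule
$\mathrm{lr}(t) = \mathrm{lr}_0 (1-t/T)^{0.9}$ (exponent 0.9, the
nnU-Net convention). Stage 1
optimizes the contrastive loss; the decoder is untouched, bitwise.
Stage 2 freezes encoder and transformer — also bitwise, which the tests
assert — and fine-tunes the decoder with the composite loss. Freezing
is implemented at the tape level: frozen parameters accumulate exactly
zero gradient. Because the encoder is fixed in stage 2, its forward
pass per volume is computed once and cached, which is what makes the
desk-scale experiments cheap.

Full-scale training of this kind of model uses 4000 + 4000 epochs of
201 iterations at `lr0 = 0.001` — roughly $8\times10^5$ optimizer
steps. The package keeps those values available in `train_config()` but
defaults to desk scale: 30 + 30 epochs, whole-volume batches of 2, and
`lr0 = 0.005` in the standard experiments, chosen once so that the
composite loss moves materially within tens of steps (with momentum
0.99 the effective rate is ~100x `lr0`; 0.001 is tuned for a step
budget four orders of magnitude larger). Gradients are clipped at a
global norm of 5, which also keeps the unscaled-exponential contrastive
option finite.

## Lesion-wise evaluation

The protocol scores detection per lesion, not per voxel:

1. the predicted mask is closed morphologically with a 1 mm kernel
   (the ground truth is used as-is);
2. 26-connected components are extracted (voxels sharing a face, edge
   or corner are adjacent);
3. each predicted component A is compared with every ground-truth
   lesion B by coverage $CV = |A\cap B|/|B|$; pairs with
   $CV \ge 0.5$ are assigned one-to-one;
4. matched pairs are true positives, unmatched predictions false
   positives, unmatched lesions false negatives;
5. per-lesion Dice $2|A\cap B|/(|A|+|B|)$ is computed for true
   positives whose ground-truth lesion is at least 3 mm long.

Size strata follow the longest 3D diameter of the ground-truth lesion —
the maximum pairwise distance between voxel centers in mm (computed on
surface voxels for large components): small $< 3$ mm, medium
$[3, 6]$ mm (closed interval: both boundaries are medium), large
$> 6$ mm. A single voxel has diameter 0 and is small. Lesion-level
reports pool TP/FN by ground-truth stratum; false positives have no
ground-truth size and are stratified by the predicted component's own
diameter. Patient-level reports compute per-patient sensitivity,
precision and mean Dice without stratification and summarize them as
mean ± SD over patients; metrics with empty denominators are reported
as missing, never as zero, and excluded from cohort means.

Decisions where the protocol description leaves room:

* **The closing kernel** is the discrete box of per-axis radius
  `max(1, round(1mm / spacing))` voxels — the diagonal-inclusive
  neighborhood notion matching 26-connectivity. A strict Euclidean ball
  of radius 1 mm cannot bridge a 1-voxel diagonal or axial gap between
  point lesions, which is precisely the "small gaps and noise" the
  closing exists to remove.
* **Multi-overlap assignment.** When one prediction covers half of two
  lesions, a greedy pass by descending coverage can strand a matchable
  lesion. The matcher instead computes a maximum-cardinality,
  maximum-coverage one-to-one assignment on the $CV \ge 0.5$ candidate
  graph (weighted bipartite matching); the tests verify agreement with
  exhaustive enumeration on all small instances.

## The phantom generator

`phantom_config()` / `generate_cohort()` emulate the statistical shape
of a multiple-metastasis T1c dataset:

* **Lesion sizes** are drawn from the three-stratum mixture observed in
  such cohorts — small 25.73%, medium 40.92%, large 33.35% — uniformly
  within each stratum (small $[1, 3)$ mm, medium $[3, 6]$ mm, large
  $(6, d_{max}]$ mm, default $d_{max} = 12$ mm). The 1 mm floor keeps
  sub-voxel lesions from silently vanishing at 1 mm spacing.
* **Lesion counts** per patient follow a decreasing law (geometric,
  $1 + \mathrm{Geom}(0.2)$, truncated at 50), matching the qualitative
  count histograms of such datasets; the exact law is a package choice
  since only histograms are reported for real cohorts.
* **Geometry.** Lesions are random-orientation ellipsoids with the
  longest axis equal to the target diameter and the other semi-axes
  shrunk by up to 40%; voxelization is by the voxel-center-in-ellipsoid
  rule, which is deterministic and orientation-robust. Centers are
  rejection-sampled so bounding spheres do not overlap.
* **Intensities.** Background level 100, contrast-enhancing lesions add
  40–80% of background (lesions are bright on T1c), Gaussian noise with
  SD 5 (5% of background), and an optional smooth multiplicative bias
  field. The mask is noise-free.

What the phantoms deliberately do **not** model: MRI physics, anatomy
(skull, vessels, ventricles — the usual sources of false positives),
partial-volume blur at lesion boundaries, non-ellipsoidal or rim-like
enhancement, and multi-sequence context. Passing tests on phantoms
therefore demonstrates that the losses, pretraining, schedule and
evaluation machinery behave as designed and that the training dynamics
move in the expected directions — not that clinical-grade accuracy
would be reached on real MRI.

## Desk-scale experiment sizes

The standard experiments in the test suite and the acceptance script
use: `48^3` volumes at 1 mm for end-to-end runs (20 phantoms for the
focal-weight comparison, 5 for freezing/determinism checks), `32^3`
volumes (10 phantoms) for the pretraining separation experiment, and a
network of base width 4, two transformer layers, `d = 16`, 2 heads.
Epoch counts are 3 pretraining + 8 fine-tuning epochs for the
focal-weight comparison and 30 pretraining epochs for the separation
experiment. These sizes were chosen once as the smallest at which the
training signals of interest are visible.

## Known limitations

* The one-sided printed focal form (`two_sided = FALSE`) zeroes the
  loss on all-background volumes; it is provided for completeness, not
  as a default.
* The literal attraction denominator (positives only) makes the
  repulsion term independent of the attraction normalization; with very
  few negatives the repulsion term is nearly constant and pretraining
  is driven mostly by attraction.
* At random initialization the token most perturbed by a lesion is not
  always the lesion's own cell — attention layers and instance
  normalization propagate any local change globally; locality is
  asserted as a top-16-of-512 rank, and the exact raster-order
  correspondence is verified separately with a pass-through encoder.
* Training at desk scale demonstrates directions (loss decreases,
  separation increases, the focal term does not hurt small-lesion
  sensitivity), not converged performance.
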