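---
title: "Attention-based multi-instance learning for 3D volumes: models and methods"
author: "foamidl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multi-instance learning for 3D volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Structural brain MRI carries diffuse, spatially scattered evidence of
neurodegenerative disease (atrophy in the hippocampus and medial temporal
lobe, ventricular enlargement), but a scan comes with a single subject-level
label — there are no voxel- or region-level annotations. `foamidl` treats
subject-level classification of registered, skull-stripped 3D volumes as a
weakly-supervised multiple-instance learning (MIL) problem: a subject is a
*bag* of `k` cubic patches (instances) of width `W`; the bag is positive if
any instance carries disease signal. The bag probability decomposes as

$$\Theta(X) = g(\phi(f(X))),$$

with `f` a shared per-patch feature extractor (PatchNet), `phi` a
permutation-invariant attention pooling over the bag, and `g` a global
classifier on the pooled representation.

# Patch location proposal

Rather than feeding all patches of the uniform `W`-partition to the network,
the package first scores every location by a group-difference test on the
training cohort: a two-sample Welch t-test on a per-subject patch summary
(default: mean intensity of the patch). The two-sided p-values are min-max
normalized, $(p - \min)/(\max - \min)$, and the `k` locations with the
smallest scores define every subject's bag, in rank order, identically across
subjects. Design points:

* **Welch, two-sided, patch-mean summary.** Group variances are not assumed
  equal. The patch-mean is the cheapest summary consistent with testing
  patch-level rather than voxel-level structure; a voxel-wise variant (one
  t-test per voxel, location scored by the mean of its voxel p-values) is
  available via `statistic = "voxel_wise"`. Neither mode is claimed to be
  uniquely correct; they agree on strongly discriminative locations.
* **No multiple-testing correction.** Selection is rank-based on the raw
  p-values and the min-max normalization is monotone, so any monotone
  correction (Bonferroni, BH) would select the same bag.
* **Degenerate locations** (zero variance in both groups) get p = 1 with a
  warning: no discriminative evidence can be extracted there.
* **Leakage.** The map is always computed from training subjects only; the
  pipeline enforces this and a test perturbs held-out subjects to verify the
  map is unchanged.

Coordinates are 0-based, cubes half-open `[origin, origin + W)`, trailing
voxels that do not fill a complete patch are dropped, and the file's native
axis order is kept (registration to a common template is assumed upstream,
so within-study consistency is what matters).

# PatchNet

Each patch passes through four 3x3x3 convolution layers (padding 1), each
followed by batch normalization and ReLU, with one 2x2x2 max-pool after the
second convolution, so a `W`-patch yields maps of side `w = floor(W/2)`.
The architecture's channel counts are configuration values; the full-scale
default is 32-64-128-128 (a 25-voxel patch gives 128 maps of 12^3), the
desk-scale default used by the synthetic pipeline is 4-8-8-8.

A **spatial attention block** is embedded after the last convolution:
channel-max and channel-average pooled maps are concatenated (2 channels),
convolved 3x3x3 to a single channel, and squashed by a sigmoid, giving a
map in (0,1) that reweights every feature channel voxel-wise. Two open
choices we fixed and document: BN precedes ReLU (conv-BN-ReLU), and the
scalar **effect score** branch — global average pooling of the *attended*
Conv4 maps followed by a linear map — reads the attended rather than the
raw maps, since the attention block is embedded in PatchNet before the
branch point. With zero-initialized attention weights the map is uniformly
0.5, so at initialization the block is a harmless rescaling.

Batch normalization needs a batch: the `k` instances of one subject's bag
form the normalization batch at train time (per-bag statistics, running
moments updated); evaluation always uses the running moments, making
inference deterministic.

# Attention MIL pooling

Per patch, the `C` channels are average-pooled to one `w^3` map; the `k`
maps stack into the global representation. Each map is reduced to a global
average (GAP) and a global max (GMP) descriptor, and both scalars pass
through a shared two-layer 1x1x1 convolution stack (channels 1 -> h -> 1,
ReLU between; default `h = max(k/4, 4)`), yielding the pre-sigmoid vectors
`A_average` and `A_max`. The patch attention map is

$$A_{patch} = \sigma(A_{average} + A_{max} + a),$$

where `a` is the effect vector, entering pre-sigmoid without rescaling and
with equal weighting of the three terms. Patch `i`'s map is scaled by
`A_patch[i]`.

Because the descriptor stack is a *per-patch scalar* transform — not a dense
map across the bag — no cross-patch mixing occurs and pooling is exactly
permutation-equivariant (tested). This is also why the "1x1x1 convolution"
reading of the shared descriptor network was chosen over a dense
`k -> h -> k` layer, which would break equivariance. Weight sharing between
the GAP and GMP paths is the default (the established shared-MLP
channel-attention design); `sharedDescriptorMLP = FALSE` unshares them.

# Global classifier, loss, training

The pooled representation (`k` maps of `w^3`) is treated as a `k`-channel
3D image and squeezed by two 3x3x3 conv-BN-ReLU stages (default widths
16-8 full scale, 8-4 desk scale), flattened, and mapped by a linear layer
to two logits with softmax. Training minimizes the mean cross-entropy
$-\frac1N \sum_n \log P(Y_n \mid X_n)$ with Adam (lr 1e-3, batch 8,
up to 100 epochs, early stopping on validation loss with patience 15 —
all configurable; plain SGD is available for analyses that need a
guaranteed descent direction at small steps). Class imbalance is not
reweighted by default; `classWeights = "balanced"` enables
inverse-frequency loss weights. All gradients are computed by hand-written
backward passes (verified against central finite differences to better
than 1e-3 relative error on every parameter group).

Ablation switches build reduced variants: `no_patchnet_cnn` replaces
PatchNet by a fixed linear embedding (2x2x2 average pooling; effect score =
patch mean), `no_attention` replaces the spatial and patch attention by
identity/unweighted pooling, and `no_fssa` skips the refinement stage.

# The fuzzy salp swarm algorithm

FSSA is a bound-constrained population minimizer used here to refine the
trained global classifier's final linear layer, with a generic
`fssaOptimize(fitnessFn, lb, ub, cfg)` interface. One run of `TMax`
iterations proceeds in two halves:

* **First half (exploration).** Each salp proposes a candidate by averaging
  three encircling points around the best-known position,
  `x_k = x_best - A_k |C_k x_best - x_i|` with `A_k = 2 a r_1 - a`,
  `C_k = 2 r_2`, `a` decaying linearly 2 -> 0 over the run; the candidate
  then takes a fuzzy step `x + alpha (x_best - x)` whose size
  `alpha` is the Gaussian fuzzy membership
  `exp(-1/2 |(f - c)/s|^m)` of the candidate's fitness `f` relative to the
  population mean `c` and SD `s` (floor 1e-12; `m = 2`), so near-average
  candidates move strongly toward the best while outliers keep exploring.
* **Second half (exploitation).** The classical salp chain: the leader
  perturbs the food source per dimension by `+/- c1 ((ub-lb) C2 + lb)`
  (branch on `C3 >= 0.5`), followers move sequentially to pairwise
  midpoints.

Throughout, greedy selection accepts a move only on strict improvement
(ties keep the incumbent, so the best-so-far trace is monotone), all
positions are clamped to the box after every update, the control parameter
`c1` decays linearly from 0.95 to 0.05 (the classical decay
`2 exp(-(4t/T)^2)` is available via `c1Schedule = "exp"`), and the
population shrinks linearly from `nMax` to `nMin` by discarding the
worst salps. Several details of this family of algorithms are genuinely
underdetermined in the literature this design draws on (the argument of
the membership function, the exact operand structure of the encircling
update, the chain order after selection); the choices above are fixed
defaults, exposed as configuration, and regression-tested: with the
exploration phase disabled and the population fixed, the loop reproduces a
hand-rolled classical salp swarm trace exactly.

`refineClassifier()` flattens the final linear layer into the decision
vector, bounds it to the current values +/- `radius` (default 0.5), seeds
the first salp with the input parameters, and minimizes the negative
validation accuracy with a small cross-entropy tie-break
(`-acc + 1e-3 CE/(1+CE)`, strictly below the accuracy resolution for up to
1000 validation subjects). Seeding plus greedy selection guarantee the
returned model's validation accuracy never falls below the input model's.
Because only the final layer moves, each validation bag's penultimate
features are computed once, making the fitness thousands of times cheaper
than a full forward pass per evaluation.

# Synthetic cohorts

`generateCohort()` emulates the two-group contrast every stage needs:
a shared smooth base field (Gaussian-filtered white noise, blur sigma 4
voxels, standardized) plays the role of common anatomy; each subject adds
i.i.d. voxel noise (SD 0.1); group-1 subjects have intensity reduced by
`d * noiseSd` inside each lesion cube (atrophy-like signal loss; the sign
is configurable). Defaults — the package's study conditions, chosen once:
48^3 volumes, one 12^3 lesion aligned to the `W = 12` partition grid at
(24, 24, 24), `d = 1.5`, 60 subjects per group. These sizes let the whole
pipeline (proposal, training, refinement, evaluation) run in minutes on a
single CPU while preserving the bag structure of the full-scale problem.

What the generator does *not* emulate — and hence what passing tests do
not show about clinical data: realistic anatomy and its between-subject
variability, registration error, intensity non-uniformity, multi-site
effects, and lesions that straddle patch boundaries. The generator's
between-subject variation is pure i.i.d. noise around a shared template,
which makes the statistical problem easier than real sMRI at the same
nominal effect size.

# Numerical choices and limitations

* Convolutions are computed via im2col + BLAS in C++ (exact, no FFT
  approximation); max-pool drops trailing voxels (floor dims).
* Sigmoid outputs are mathematically in (0,1) but saturate to 1.0 in double
  precision beyond ~|x| = 37; invariance tests therefore use moderate
  parameter scales.
* Ties: patch selection breaks p-value ties lexicographically by
  coordinate; greedy selection keeps the incumbent; channel-max pooling
  takes the first maximal channel for the backward pass.
* The degenerate `radius = 0` refinement box returns the model unchanged.
* Reports are deterministic functions of (config, seed); logs carry no
  timestamps so reruns are byte-identical.
* Hold-out and cross-validation splits are stratified by label (the small
  cohorts this package targets make unstratified splits too variable).
* The hard-call threshold for ACC/SEN/SPE defaults to 0.5; AUC is
  threshold-free (rank-based Mann-Whitney with ties counted 1/2).
* Multi-class staging, longitudinal modeling, and gradient-based saliency
  maps are out of scope; attention weights per patch are exported as CSV
  for downstream visualization instead.
* **Attention interpretability needs a non-saturated task.** When the bag
  classification problem is easy enough that the cross-entropy collapses
  within a few epochs (as it does at the default synthetic conditions),
  the attention parameters receive almost no gradient afterwards: patch
  attention weights stay near their sigmoid(0) = 0.5 initialization plus
  small content-driven offsets, and the identity of the top-weighted patch
  is then decided by initialization rather than by class evidence — even
  though the effect scores themselves measurably separate the classes at
  the signal-carrying patch. Classification quality (AUC) is unaffected;
  only the "top attention marks the pathological site" reading becomes
  unreliable. On hard tasks, where training pressure persists, attention
  has both the time and the incentive to concentrate on discriminative
  patches; treat desk-scale attention maps as qualitative.
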