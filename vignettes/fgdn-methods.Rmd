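---
title: "Functional graph discriminative networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional graph discriminative networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The classification problem

Resting-state fMRI cohorts for case-control studies (the motivating use case
is autism spectrum disorder versus healthy controls) are usually reduced to
one functional-connectivity matrix per subject: an N x N summary of the
statistical dependence between the BOLD time series of N atlas regions.
Off-the-shelf classifiers treat the vectorized matrix as a flat feature
vector and ignore that its rows live on a network. The model implemented
here keeps the network structure explicit: it builds one *graph template*
per diagnostic class from training data, runs every subject's connectivity
rows through a spectral graph-convolution network once per template, and
asks which class's template the subject's features are most consistent
with.

## Feature pipeline

**Covariance estimation.** Each subject's T x N time-series matrix is
column-demeaned and its covariance estimated with the Ledoit-Wolf shrinkage
estimator, `(1 - alpha) S + alpha (tr(S)/N) I`, where `alpha` is the
analytically optimal shrinkage intensity. Shrinkage matters twice: it
stabilizes estimates when T is comparable to N, and it guarantees a
positive-definite matrix, which the tangent step requires. Time series are
demeaned but *not* variance-scaled by default; whether upstream pipelines
standardize is acquisition-specific, so `standardize` is exposed as a
configuration switch (default `FALSE`, keeping covariance on its native
scale).

**Tangent-space embedding.** Covariance matrices live on the SPD manifold,
where Euclidean operations (class means, linear layers) are distorted. The
pipeline therefore maps each covariance `C` to the tangent space at a
reference point `G`: `logm(G^{-1/2} C G^{-1/2})`. The reference is the
affine-invariant geometric mean of the *training* covariances, computed by
the standard fixed-point iteration (initialized at the Euclidean mean,
iterated until the mean log-deviation falls below 1e-6 in Frobenius norm,
cap 50 iterations). The geometric mean is the canonical choice for tangent
embedding of SPD matrices; the Euclidean mean is kept as a fallback
(`tangent_mean = "euclidean"`) for degenerate or very small training sets.
Pearson correlation features (`feature_kind = "correlation"`) are available
as the simpler alternative used for baseline comparisons.

Two leakage rules are enforced throughout and asserted at run time by
id-set bookkeeping: the tangent reference and the class templates are
fitted on training subjects only (held-out subjects are embedded with the
stored reference), and inside the training routine they are fitted on the
non-monitor portion so early stopping never touches data that shaped the
features.

## Graph templates

For each class, the element-wise mean of the training subjects' feature
matrices defines N node features (its rows). Edges come from a KNN rule
with a Gaussian kernel: node i keeps its k nearest neighbours by Euclidean
row distance (the per-node cutoff is the k-th neighbour distance; ties at
the cutoff break by ascending node index, making templates a deterministic
function of the training fold), the kernel width `theta` is the mean of all
retained directed distances, and retained pairs get weight
`exp(-d^2 / (2 theta^2))`. The directed selection is symmetrized by union
(`W <- pmax(W, t(W))`) rather than intersection: union guarantees every
node keeps at least k edges (no isolated nodes entering the Laplacian) and
keeps `W` symmetric. Self-loops are excluded; coincident rows get weight 1.

The default k is 20, the conventional neighbourhood size for connectome
graphs at atlas resolutions of 100+ regions. On smaller synthetic atlases
the training pipeline clamps k to N - 1 (and records the value used);
`build_template` itself treats k >= N as an error.

A test subject contributes only node features: its own connectivity rows
are attached to the ASD template and to the HC template, giving two graphs
with identical features and different edges. The features pass through
unmodified — the two class scores differ only through the graph structure.

## The network

The spectral convolution filters node features with a degree-K Chebyshev
polynomial of the rescaled normalized Laplacian
`Lt = 2 L / lambda_max - I`, `L = I - D^{-1/2} W D^{-1/2}`:
`sum_k T_k(Lt) X theta_k`, with `T_k` evaluated by the three-term
recursion applied directly to the feature matrix. `lambda_max` is computed
exactly by eigendecomposition rather than the common `lambda_max ~ 2`
shortcut — at N <= 128 the exact computation is negligible and removes an
approximation. Degree-0 nodes get the isolated-node convention `L_ii = 1`.

The architecture is: Chebyshev convolution (N input channels to 64 kernels,
K = 3) -> PReLU -> dropout (0.1) -> Chebyshev convolution (64 to 64) ->
PReLU -> dropout -> flatten -> fully connected layer (128 hidden units) ->
PReLU -> 2 sigmoid output units (unit 1 = ASD, unit 2 = HC). One network
with one parameter set serves both passes: the ASD graph is run and unit 1
read, the HC graph is run and unit 2 read. Shared weights are the natural
reading of a single model fed two graphs; separate towers would double the
parameters with nothing to constrain the second tower. The hidden width 128
is a package default (config-exposed); the convolution width 64, K = 3 and
the dropout placement after each convolution activation follow the standard
protocol for this architecture. A subject is called ASD when its ASD-unit
output strictly exceeds its HC-unit output; exact ties go to HC.

The loss is the summed (not averaged) binary cross-entropy over both units,
with targets (1,0) for ASD and (0,1) for HC and outputs clipped to
`[1e-7, 1 - 1e-7]` to keep the loss finite. Gradients are computed by
hand-written backpropagation through both passes; a finite-difference check
on every parameter class is part of the test suite. Parameters are
initialized Glorot-uniform with PReLU slopes at 0.25, biases at zero.

## Training protocol

Adam (learning rate 1e-4, weight decay 5e-4 added L2-style to all
gradients, betas 0.9/0.999), mini-batches of 16, dropout 0.1 while
training. Before training, 10% of the training subjects (stratified by
class, at least one per class) are split off as a monitoring set; after
each epoch the monitoring accuracy is evaluated, and training stops once
`patience = 20` epochs pass without a new best, restoring the
best-monitoring-epoch parameters. The stopping horizon (`max_epochs = 300`)
and patience are package defaults since only the stopping *criterion*
(best monitoring accuracy) is prescribed by the protocol; both are
config-exposed. The monitoring split is per training set — inside
cross-validation each fold draws its own split — and stratified, which
stabilizes the small monitor sets that 10% of a fold produces. Every
random choice (splits, initialization, batch order, dropout masks) derives
from the single config seed, so reports are exactly reproducible.

## Evaluation harness

`cross_validate` uses stratified random fold assignment (the conventional
5- and 10-fold settings), refits the entire pipeline inside every fold and
reports accuracy, Mann-Whitney AUC (ranking score `p_asd - p_hc`, ties
counted half), sensitivity and specificity as mean (SD) over folds.
`leave_one_site_out` holds each acquisition site out in turn.
`learning_curve` subsamples each fold's training set (stratified) at given
fractions while the held-out fold stays fixed; at fraction 1.0 it
reproduces `cross_validate` bit for bit under the same seed.

`region_discriminability` measures per-region class signal by occlusion:
for region r, the node-feature *rows* of all other regions are clamped to
zero (templates untouched), each fold's trained model is fine-tuned on its
masked training set — 30 epochs at one tenth of the learning rate, no
early stopping, a deliberately short budget since only re-calibration to
the masked input is wanted — and the masked held-out fold is scored. A
region's discriminative weight is its mean masked validation accuracy;
`pct_exceeded` counts the share of other regions it beats under a paired
two-sided t-test across folds at p < 0.05, with no multiplicity
correction, matching the per-pair "significantly better than x% of
regions" reading. Row-only masking is the default because a retained
region's row already carries its connectivity to every other region;
zeroing the reciprocal columns as well (`mask_columns = TRUE`) is offered
for the stricter reading under which only within-mask entries survive.

## The synthetic cohort generator

Real multi-site case-control data cannot ship with a package, so every
experiment runs on generated cohorts with planted, known structure. The
generator builds an HC covariance from a random sparse partial-correlation
structure (unit variances), adds +-`effect_size` to the off-diagonal
entries among a small set of `signal_regions` to form the ASD covariance
(eigenvalue-clipped back to SPD at 1e-6), draws each subject's covariance
as class covariance plus a symmetric Gaussian perturbation
(`subject_noise`), scales variances by an evenly spaced per-site factor
(`1 +- site_shift`), and emits zero-mean Gaussian time series with that
covariance. Site effects enter as variance scaling rather than mean shifts
because connectivity features are second-moment statistics — a mean shift
would vanish in the covariance. Temporal autocorrelation is off by default
(an AR(1) option exists, transformed so the stationary covariance is
unchanged): white noise already exercises every estimator in the pipeline.

Default conditions: 100 subjects per class, 16 ROIs, 150 timepoints,
3 sites, effect size 0.4 on the edges among regions {4, 8}, subject noise
0.1, site shift 0.1. Two signal regions make region-recovery experiments
well-posed; noise and site-shift scales are set so that the planted effect
(about 0.4 in covariance units against a sampling SD of roughly
`sqrt(2/T) ~ 0.12` plus subject noise 0.1) is clearly learnable but not
trivial — a Bayes-style rule on the true covariances is near-perfect, which
the test suite verifies so that recovery tests are achievable rather than
vacuous. Cohort difficulty still varies visibly across generator seeds
(five-fold accuracies roughly in the high 70s to high 80s), as the random
base covariance and perturbation sign change the separability of a given
draw.

What the generator does *not* emulate: BOLD hemodynamics, motion and
scanner artifacts, mean (first-moment) site effects, heavy-tailed noise,
and atlas misregistration. Passing recovery tests on these cohorts
demonstrates that the pipeline learns planted second-order structure under
multi-site variance heterogeneity; it does not certify performance on real
acquisitions.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script size their simulations to run on
a single CPU: unit and property tests use 4-8 ROI fixtures and cohorts of
6-30 subjects; the end-to-end recovery and learning-curve checks use the
default 200-subject, 16-ROI cohort; the region-recovery check uses 48
subjects per cohort across three generator seeds with the fine-tuning
budget shortened to 15 epochs (the package default stays 30). The
acceptance script runs five-fold cross-validation, leave-one-site-out and
the two learning-curve endpoints on the default cohort.

## Known limitations

- Training is full-precision CPU R; at 128 ROIs and ~900 subjects a
  cross-validated run takes hours, not minutes. The architecture is small
  by deep-learning standards and the implementation is vectorized over
  batches, but there is no GPU path.
- The tangent fixed-point iteration assumes well-conditioned covariances;
  Ledoit-Wolf shrinkage makes that hold in practice, but raw sample
  covariances with T < N are rejected rather than repaired.
- AUC is reported as `NA` for single-class test sites in leave-one-site-out
  rather than being imputed.
- The region analysis inherits the usual caveats of occlusion-based
  importance: regions whose signal is redundant with others can score low
  individually.
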