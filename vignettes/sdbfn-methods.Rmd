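---
title: "Sparse dynamic brain functional networks by hyper-graph manifold regularization: models and methods"
author: "sdbfn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sdbfn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbfn)
```

## The problem

Resting-state fMRI yields one BOLD time series per atlas region (ROI).
Functional connectivity between regions is not static: sliding-window
analysis captures how the correlation structure drifts over a scan, and
summaries of these *dynamic brain functional networks* (DBFNs) are used as
features for classifying patients — here, a mild-cognitive-impairment-like
positive group — against controls. Raw windowed Pearson networks are dense
and noisy. This package estimates *sparse* dynamic networks by penalized
fits that keep the windowed correlation structure while (i) zeroing weak
edges through an L1 penalty and (ii) smoothing connectivity profiles over a
hyper-graph that encodes which groups of regions behave similarly — a
*hyper-graph manifold regularizer* that can express relations among more
than two regions at once, which an ordinary graph Laplacian cannot.

## Sliding-window Pearson networks

A subject is a matrix $X \in \mathbb{R}^{Q \times P}$ (Q time points, P
regions). For window width $N$ and step $S$ the package takes the
contiguous windows starting at $1, 1+S, 2S+1, \dots$, giving
$K = \lfloor (Q-N)/S \rfloor + 1$ windows; a trailing partial window is
dropped (the count is exact when $S \mid Q-N$). Within each window every
column is centered and scaled to unit Euclidean norm, so the Gram matrix
$W^{(k)} = X^{(k)\top} X^{(k)}$ *is* the matrix of windowed Pearson
correlations: symmetric, unit diagonal, entries in $[-1, 1]$, and positive
semi-definite by construction. Standardization is per window, not global —
otherwise the Gram matrix would not equal the windowed correlation that the
downstream objective treats as its target.

## The KNN hyper-graph and its Laplacian

For each window's $P \times P$ matrix $W$, one hyper-edge is built per
region: edge $e_b$ contains its *center* $b$ plus the $k$ regions whose
connectivity profiles (rows of $W$) are nearest to $b$'s in Euclidean
distance. When rows $b$ and $j$ are compared, columns $b$ and $j$ are
dropped, so the structural unit diagonal never contributes. Ties are broken
deterministically toward the lower region index. Every edge therefore has
degree $k + 1$ and the incidence matrix $H$ is $P \times P$ with unit
diagonal.

With positive edge weights $a(e_b)$ (unit by default; a Gaussian kernel on
the mean center-to-neighbor distance is available), vertex degrees
$d(v) = \sum_b a(e_b) H(v, b)$ and edge degrees $\delta(e_b) = \sum_v
H(v, b)$ define the normalized hyper-graph Laplacian

$$ L^h \;=\; I - D_v^{-1/2} H A D_e^{-1} H^\top D_v^{-1/2}. $$

$L^h$ is symmetric positive semi-definite and annihilates
$D_v^{1/2}\mathbf{1}$ for a connected hyper-graph; both properties are
asserted in the test suite over random instances. Edge weights default to
unit because nothing in the estimator requires a particular weighting and
unit weights keep the operator scale-free; the Gaussian option is provided
for sensitivity analyses.

By default one hyper-graph is built *per window*, since the regularizer
enters each window's objective; a single hyper-graph from the mean Pearson
network can be requested (`hypergraphScope = "mean"`) when the analyst
prefers one shared geometry per subject.

## The SHMR estimator

Per window, with $S_0 = X^{(k)\top}X^{(k)}$ the Pearson matrix, SHMR
minimizes

$$ \lVert W - S_0 \rVert_F^2 \;+\; \lambda \lVert W \rVert_1
   \;+\; \beta\, \mathrm{tr}(W^\top L^h W), $$

by proximal gradient descent: a gradient step on the smooth part followed
by the elementwise soft threshold
$\mathrm{sgn}(w)\max(|w| - t, 0)$. The implementation follows the
conventional update rule in which the manifold term contributes
$\beta L^h W$ to the gradient step. Because the exact gradient of
$\beta\,\mathrm{tr}(W^\top L^h W)$ is $2\beta L^h W$, that update is the
exact proximal gradient iteration for the composite objective in which the
manifold term carries weight $\beta/2$. Two consequences, both deliberate:

* the `objectiveTrace` recorded in a [SolveResult-class] is that
  internally consistent composite, which is guaranteed non-increasing
  under the default Lipschitz step $\alpha = 1/(2 + \beta\,
  \lambda_{\max}(L^h))$;
* `shmrObjective()` exposes the nominal $\beta$-weighted form for users
  who want to evaluate the printed objective; the two coincide when
  $\beta = 0$.

Further solver choices, all of which the estimator's definition leaves
open:

* **Initialization** $W^{(0)} = S_0$: the unregularized optimum, which
  makes the $\lambda = \beta = 0$ reduction exact in one iteration.
* **Threshold scaling.** The proximal operator of $\lambda\lVert\cdot
  \rVert_1$ at step $\alpha$ thresholds at $\alpha\lambda$
  (`thresholdScaling = "step_scaled"`, the default and the mathematically
  consistent choice). A `"literal"` mode thresholds at $\lambda$ itself,
  reproducing the soft-threshold rule as often printed; with $\beta = 0$
  it converges to $\mathrm{sgn}(s)\max(|s| - \lambda, 0)$ rather than
  $\lambda/2$.
* **Stopping**: relative objective change below `tol` ($10^{-6}$) or
  `maxIter` (500) iterations.
* **Symmetrization**: the returned estimate is $(W + W^\top)/2$. With
  symmetric $S_0$ and $L^h$ the iterates stay symmetric, so this is a
  numerical safeguard rather than a correction.

Setting $\lambda = 0$ gives the HMR estimator, $\lambda = \beta = 0$
returns the Pearson network unchanged; both reductions are tested bitwise.
The soft threshold makes the off-diagonal support non-increasing in
$\lambda$ at fixed $\beta$ (also under test).

## The regression baselines (SR, MR, SMR)

The comparison family replaces the correlation fit with self-regression of
the standardized window $X$:

$$ \lVert X - XW \rVert_F^2 + \lambda \lVert W \rVert_1
   + \beta\,\mathrm{tr}(W^\top L W), $$

where $L = I - D^{-1/2}\lvert S\rvert D^{-1/2}$ is the simple-graph
Laplacian of the window's Pearson matrix, with degrees computed on
$\lvert S \rvert$ — correlations are signed, and a real $D^{-1/2}$
requires nonnegative degrees. $\beta = 0$ gives SR, $\lambda = 0$ gives
MR, both positive give SMR. The diagonal of $W$ is clamped to zero after
every proximal step: without that constraint $W = I$ trivially zeroes the
fit term. The solver starts from $W = 0$, uses the same gradient-rule
convention as SHMR (so the same $\beta/2$ trace bookkeeping), the
Lipschitz step $1/(2\lambda_{\max}(X^\top X) + \beta\lambda_{\max}(L))$,
and symmetrizes on return. Because the zero-diagonal problem decouples
into one lasso per column, the test suite cross-checks it against an
independent coordinate-descent lasso solver.

## Features, selection, classification

Each window matrix is summarized by weighted local clustering
coefficients. Weights are taken in absolute value (cube roots of negative
weights would leave $[0,1]$), the diagonal is ignored, and weights are
normalized by the largest off-diagonal magnitude, making the coefficients
scale invariant. The default is the Onnela triangle form

$$ C_i = \frac{2}{k_i(k_i - 1)} \sum_{j < h \in v_i}
   \left( \hat w_{ij}\, \hat w_{ih}\, \hat w_{jh} \right)^{1/3}, $$

with $v_i$ the nonzero neighbors of $i$ and $C_i = 0$ for $k_i < 2$; a
`"literal"` mode computing the degree-normalized sum of cube-rooted
incident weights $2\sum_{j \in v_i} \hat w_{ij}^{1/3} / (k_i(k_i-1))$ is
kept for comparison — it is a strength measure, not a triangle count, and
is not bounded by 1 at $k_i = 2$. Per subject, the $K$ per-window vectors
are averaged into one length-$P$ feature vector (`aggregate = "mean"`);
concatenation is available but multiplies the feature dimension by $K$,
which the cohort sizes here cannot support.

Classification is repeated stratified $k$-fold cross-validation (default
$10 \times 10$): inside every training fold, a two-sample pooled-variance
t-test keeps features with $p < 0.05$ (no multiple-testing correction, by
design — selection is a filter, not an inference), and a linear-kernel SVM
with $C = 1$ is fit on them. Feature selection is nested inside the folds
by default; `nested = FALSE` reproduces the optimistic full-data protocol
for comparison, and a canary test verifies that the nested protocol does
not show the unnested protocol's inflation on null data. If no feature
passes, the single smallest-p feature is used so the classifier is always
defined. Features are standardized within each training fold before the
SVM fit (the library default): clustering coefficients live on a small
numeric range, and at fixed $C$ an unscaled fit lets the regularizer
collapse the weight vector, degenerating predictions toward a single
class while leaving the decision-value ranking (and hence AUC) almost
untouched — a pathology worth knowing about when comparing published
sensitivity/specificity pairs. Per repetition, out-of-fold predictions are pooled into one
confusion matrix (ACC, SEN, SPE — positive class = patient-like) and
pooled decision values give the AUC; means and standard deviations are
reported over repetitions. All randomness is a pure function of the seed.

## The synthetic cohort generator

No clinical data ship with the package; the generator exists so the whole
pipeline can be exercised and its statistical behavior tested. It emulates
the *shape* of a two-group resting-state cohort: $P$ regions partitioned
into modules; within-module correlation `rhoWithin`, between-module
`rhoBetween`; in the positive group, designated modules have their
within-module correlation attenuated by `effectDelta` (the functional
disconnection direction); temporal autocorrelation by a recursive AR(1)
filter; white observation noise on top. Per-subject seeds derive from the
master seed and are recorded in the manifest together with any covariance
shrinkage (non-PSD block patterns are shrunk minimally toward the
identity; shrinkage above 0.5 is refused).

Defaults, chosen once as a plausible small-cohort operating point and then
left alone: 40 + 40 subjects, $P = 30$ in 6 modules of 5, $Q = 120$,
`rhoWithin` 0.6, `rhoBetween` 0.1, `effectDelta` 0.3 on modules 1–2,
`arCoeff` 0.3, `noiseSd` 0.5. Two analytic facts worth knowing when
interpreting simulations: the AR filter inflates the marginal variance to
$1/(1-\phi^2) \approx 1.10$, and the added noise then attenuates every
correlation by the factor $1.10 / (1.10 + 0.25) \approx 0.81$, so the
*observed* within-module correlations are about 0.49 (controls) versus
0.24 (attenuated modules, positive group).

What the generator does **not** emulate: hemodynamic response convolution
(AR(1) is a deliberate simplification), scanner drift and motion,
physiological noise spectra, spatial autocorrelation between neighboring
parcels, and subject-level heterogeneity in module layout. Passing tests
on this generator therefore demonstrate correctness and calibration of the
*pipeline*, not clinical performance on real fMRI.

## Problem sizes used by the shipped simulations

The test suite runs the full pipeline at window width 50, step 5 (15
windows at $Q = 120$): null calibration on twenty 20 + 20-subject cohorts
with `effectDelta = 0`, and signal recovery on three 40 + 40-subject
cohorts (seeds 101–103) at the default operating point ($k = 7$,
$\lambda = 2^{-4}$, $\beta = 2^{-3}$). The acceptance script repeats the
signal benchmark and null calibration from the supplied seed and
additionally reports the PC baseline, the off-diagonal sparsity fraction
of the SHMR networks, and the window count at the clinical acquisition
geometry (170 volumes, width 50, step 1). These sizes are the package's
own choices for routine verification; nothing prevents larger runs through
the same functions.

## Degenerate inputs and numerical conventions

* Zero-variance region within a window: error naming the region (a
  correlation is undefined there).
* Isolated hyper-graph vertex (impossible under centered construction,
  checked anyway), non-binary incidence, nonpositive edge weights:
  errors.
* All-zero weight matrix in `localClustering()`: the zero vector, not an
  error.
* Fixed-step solves that overshoot raise a divergence error rather than
  returning NaNs.
* Symmetry is enforced to $10^{-10}$ throughout; PSD assertions allow
  $-10^{-10}$ for eigenvalue round-off.

## Known limitations

* The hyper-graph is built by KNN on connectivity profiles; neighborhood
  size $k$ matters and no data-driven selection is provided (the package
  exposes `sweepGrid()` for sensitivity analyses instead).
* The solvers are plain proximal gradient with constant step; for the
  problem sizes of interest ($P \le$ a few hundred) this converges in tens
  of iterations, and no accelerated or ADMM variants are included.
* At the default noise level the synthetic two-group separation is
  intentionally modest; the sparse estimators improve on the dense PC
  baseline but the absolute accuracies reported by the acceptance script
  should be read as properties of the simulation, not of any clinical
  population.
* Binary classification only; no multi-class support.
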