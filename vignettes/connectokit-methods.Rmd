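---
title: "Individual functional network mapping and edge-centric analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual functional network mapping and edge-centric analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectokit)
```

connectokit implements an individual-level functional connectomics
pipeline for resting-state BOLD data: personalized large-scale network
mapping by spatially regularized non-negative matrix factorization
(NMF), node-wise and edge-wise functional network connectivity (FNC),
graph-theoretic network attributes with small-world indices, edge
community detection, co-fluctuation amplitude (RSS) statistics, and an
ANCOVA/FDR group-comparison layer. This vignette documents the models,
the tunable parameters, the synthetic cohort generator used for
validation, and the numerical choices made where the design was open.

## The decomposition model

Each subject's masked voxel time series are arranged as a $V \times T$
matrix. Before decomposition every voxel series is shifted by its
minimum and divided by its maximum, so all values lie in $[0, 1]$
(`normalize_nonnegative()`; constant voxels map to zeros). The
transposed matrix $X \in \mathbb{R}^{T \times V}_{\ge 0}$ is factorized
as $X \approx W H$ with non-negative network time courses
$W \in \mathbb{R}^{T \times K}$ and spatial loadings
$H \in \mathbb{R}^{K \times V}$, minimizing

$$
\|X - WH\|_F^2 \;+\; \beta\,\mathrm{tr}(H L H^\top)
\;+\; \alpha\,\|H - H_{\mathrm{prior}}\|_F^2 ,
$$

where $L = D - A$ is the combinatorial Laplacian of the voxel lattice
adjacency graph (6-neighbourhood by default; 18 and 26 available). The
Laplacian term rewards spatially smooth maps, the prior term anchors a
subject's loadings to a group atlas. Optimization uses Lee–Seung
multiplicative updates extended with both quadratic penalties; every
update has the standard auxiliary-function guarantee, and the recorded
objective trace is non-increasing (asserted in the test suite). A
floor of $10^{-12}$ in the update denominators prevents division by
zero. Convergence is declared when the relative objective change drops
below `tol` ($10^{-5}$ by default) or after `max_iter` (500)
iterations. After convergence each row of $H$ is max-normalized and the
corresponding column of $W$ rescaled inversely, which fixes the scale
indeterminacy without changing $WH$.

### Regularization weights

Both weights are scale-adaptive by default so they track the data
energy: $\beta = 10^{-3}\,\|X\|_F^2 / V$ and
$\alpha = 10^{-1}\,\|X\|_F^2 / V$ (the prior term is active only when a
prior is supplied). We deliberately keep the spatial weight two orders
of magnitude below the prior weight: on cohorts with known ground-truth
maps, a spatial weight ten times larger visibly blurs adjacent networks
into one another (single-run truth-row correlation drops from about
0.82 to 0.74), while the chosen value retains genuine smoothing and
recovers the generating atlas. The prior weight is strong by design —
it is what keeps row $k$ of every subject atlas aligned with row $k$ of
the group atlas, so no post hoc network matching is needed. When the
question is how far an individual deviates from the group topography, a
weaker prior (e.g. `alpha = 0.1`) lets the subject's own map dominate;
the personalization tests exercise both regimes.

### Group atlas and consensus

The group stage concatenates the normalized time series of up to 50
subjects along time (a 50-subject, 170-frame cohort gives an
$8500 \times V$ matrix) and decomposes the pooled matrix `repeats`
times from fresh random non-negative initializations. The pooled
$\mathrm{repeats} \times K$ rows are then clustered into $K$ groups by
spectral clustering (Ng–Jordan–Weiss on the pairwise row-correlation
similarity, k-means in the embedding, with re-runs on empty clusters),
and each cluster's mean row, max-normalized, becomes one consensus
atlas row. The configuration default is 50 repeats; desk-scale
validation uses 10, the smallest count at which consensus recovery of a
known 17-network atlas is stable (one-to-one row correlation 0.93 at 10
repeats versus 0.80 at 5 on the default cohort). Whether repeated runs
should also resample subjects is ambiguous in the field; we re-decompose
the same concatenated matrix with new initializations, which is what the
consensus step needs (diverse local minima of the same problem).

## Connectivity layers

Node-wise FNC is the $K \times K$ Pearson correlation matrix of the
network time courses. Edge time series z-score each course with the
population ($1/T$) variance and take the frame-wise product
$e_{ij}(t) = z_i(t)\,z_j(t)$ for all $E = K(K-1)/2$ pairs in
lexicographic order; under this scaling $\frac1T\sum_t e_{ij}(t)$
equals the Pearson correlation exactly, an identity the suite asserts at
$10^{-10}$ for every subject. Without the z-scoring the identity fails,
which is why the implementation standardizes even though product
notation alone does not demand it. The $E \times E$ correlation matrix
of edge series is the edge-wise FNC (eFC); with $K = 17$ this is the
136-edge layer.

The RSS profile $\mathrm{rss}(t) = \sqrt{\sum_e e_e(t)^2}$ summarizes
the global co-fluctuation amplitude per frame. The top and bottom
fractions (5% by default, $k = \lceil \mathrm{frac}\cdot T\rceil$
frames per tail, ties broken toward earlier frames for determinism)
define the T/N/B amplitude levels; `tail_amplitude()` is the mean RSS
of a tail and `count_transitions()` counts the $T-1$ consecutive-frame
level transitions, self-transitions included.

## Graph attributes

Correlation matrices are thresholded by the significance of each entry
(two-sided t-transform with $T-2$ degrees of freedom, $p < \alpha$,
default 0.05) and binarized. Significance is assessed on $|r|$, so
significant negative couplings are kept as edges; a `positive_only`
flag switches to positive-only thresholding. Metrics use the classic
binary definitions: mean nodal clustering $C_p$ (zero for degree-<2
nodes), characteristic path length $L_p$ averaged over connected pairs
only, global efficiency as the mean inverse distance with disconnected
pairs contributing zero (stated explicitly because thresholded 17-node
graphs can fragment), local efficiency as the mean global efficiency of
each node's open neighbourhood subgraph, degree assortativity as the
end-node degree correlation over edges, and Newman modularity $Q$ of
the greedy-agglomerative partition. Small-world indices compare against
degree-preserving double-edge-swap nulls: $\gamma = C_p /
\langle C_p^{\mathrm{null}}\rangle$, $\lambda = L_p /
\langle L_p^{\mathrm{null}}\rangle$, $\sigma = \gamma / \lambda$, with
100 nulls by default and the conventional criterion recorded as
$\gamma > 1$, $\lambda \in [0.8, 1.2]$, $\sigma > 1$. All metrics are
validated against exhaustive brute-force implementations on every graph
with up to five nodes and a seeded sample of six-node graphs; the full
$2^{15}$ enumeration at six nodes adds minutes of pure duplication for
no additional structure, so a density-spanning sample stands in.

## Edge communities

The optimal module count comes from recursive Newman spectral
bipartitioning of the signed eFC (positive and negative parts each get
their own configuration null; the leading eigenvector of the restricted
modularity matrix proposes each split, a single-swap refinement pass
improves it, and recursion stops when the modularity gain is no longer
positive). Edges are then grouped by k-means with correlation distance
$1 - r(\mathrm{row}, \mathrm{centroid})$, mean-row centroids,
farthest-point re-seeding of empty clusters, and the best of
`n_restarts` runs. Communities map back to networks by counting, for
each edge in a community, its two endpoint networks — so each column of
the count matrix sums to twice the community size. Community-level
connectivity correlates the mean edge time series of each community;
since communities are sets of edges, the representative is built from
edge series rather than node series (a flag could expose the
alternative, but the edge basis is the natural one).

One identifiability point is worth recording. Modularity compares
observed weights with a configuration null; a partition whose
between-community structure exactly matches that null is invisible to
any modularity-based count. Per-subject eFC at 170 frames sits close to
this regime for equal independent blocks (finite-sample correlation
noise, of order $1/\sqrt{T}$, inflates the negative-part null), so the
pipeline detects communities on the cohort-average eFC, where averaging
over subjects restores identifiability. The validation suite plants an
8-community structure at within-community correlation 0.5 and recovers
both the count and the partition from 10-subject cohort averages in
every replicate.

## Statistics layer

Group differences use an ANCOVA with mean framewise displacement as
covariate: a type-II partial F-test of the group factor in
$y \sim \mathrm{group} + \mathrm{FD}$, with
$\mathrm{df} = (g-1,\; n-g-1)$, falling back to one-way ANOVA with a
warning when the covariate is collinear with the groups. Features whose
omnibus test passes $p < 0.05$ receive all pairwise pooled-variance
t-tests (Welch available by flag), and Benjamini–Hochberg FDR at
$q = 0.05$ is applied across the pooled family of all gated
pair-by-feature tests — the family definition is a choice; a flag could
scope it per feature, but pooling matches correction applied to the
post-hoc stage as a whole. Clinical associations are Pearson
correlations with t-based p-values and BH-FDR across the full
metric-by-score grid. Calibration is tested directly: the ANCOVA
rejects 5% of null simulations within binomial error (1000 replicates
at $n = 60$), and the BH implementation is checked against a
brute-force step-up on every subset of eight p-values.

## The synthetic cohort generator

The generator exists so every stage can be validated against known
ground truth; its defaults are the study conditions of the validation
suite. A cohort design fixes four groups (TD, ASD, ADHD-combined,
ADHD-inattentive), 180 frames at TR = 2 s, $K = 17$ networks, and a
desk-scale $V = 2000$ voxel lattice. Ground truth consists of:

- a $K \times V$ atlas of contiguous dominant blocks on the voxel
  lattice with Gaussian falloff (half-block-width scale, so boundary
  voxels still load clearly on their own network) over a 0.01 floor;
- one latent covariance per group — equicorrelation 0.2 plus any
  planted deltas on named network pairs, projected back to SPD by
  eigenvalue clipping (the construction errors if a requested delta
  cannot survive projection);
- a planted partition of the $K(K-1)/2$ network pairs into edge
  communities;
- the clinical-score generative coefficients.

Subjects draw a per-subject latent covariance (group covariance plus
symmetric jitter, SD 0.05, re-projected), a stationary AR(1) latent
series with coefficient 0.3 (BOLD-like smoothness), spatial loadings
perturbed with truncated Gaussian noise (SD 0.05), and i.i.d. Gaussian
voxel noise at a signal-to-noise variance ratio of 4 — moderate for
cleaned BOLD, and deliberately harder than noiseless. Motion is a
cumulative-sum Gaussian random walk over six parameters (rotations in
radians, scaled 1/50 of translations) calibrated so that the expected
mean FD matches the group level (defaults 0.13/0.18/0.22/0.33 mm,
matching the real cohorts this design emulates). Each subject
additionally draws a lognormal multiplier (log-SD 0.5, mean-corrected)
on the motion level: within-group FD spread is a feature of real
cohorts, and without it mean FD becomes collinear with the group factor
and an FD-covaried ANCOVA loses its power by construction. Clinical
scores are generated post hoc as
$r \cdot z(\mathrm{metric}) + \sqrt{1-r^2}\,\varepsilon$ from
ground-truth metrics, the simplest construction that hits a target
correlation.

What the generator does not emulate: hemodynamic response convolution,
scanner drift and physiological noise, spatial autocorrelation of the
noise, site effects, and the anatomy of real network topographies.
Passing tests therefore demonstrate that the algorithms recover the
structure they assume, at realistic noise and motion levels — not that
the pipeline is robust to everything real data contains.

## Validation scales and reproducibility

Validation runs at sizes chosen to exercise the method, not the
hardware: the default cohort (V = 2000, 20 subjects, 10 consensus
repeats) for reconstruction accuracy and atlas recovery; 20 replicate
cohorts at $K = 6$, $V = 150$, 30 subjects per group for the planted
FNC effect (delta 0.4, detected through the full netmap → connectivity
→ ANCOVA+FDR chain in over 80% of replicates, with null cohorts gating
at the nominal 5%); and 20 replicate 10-subject cohorts for the planted
8-community structure. Every stochastic step takes an explicit seed,
and the pipeline driver derives per-stage seeds deterministically from
one global seed, so identical configurations reproduce identical
outputs, checksums included.

## Known limitations

- Multiplicative NMF updates converge to local minima; consensus over
  repeats mitigates but does not eliminate initialization dependence.
- The minimum-shift normalization adds a per-voxel constant, so even
  noiseless rank-$K$ latent data is rank $K{+}1$ after normalization;
  reconstruction correlations saturate slightly below 1.
- The module count is only as identifiable as the eFC structure is
  distinguishable from the configuration null (see above); on single
  short scans the count is noisy even when the partition itself is
  recovered almost perfectly.
- Graph metrics assume binary graphs after significance thresholding;
  weighted variants are out of scope.
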