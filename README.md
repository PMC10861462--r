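# connectokit

Individual-level functional connectome mapping and edge-centric network
analysis for resting-state fMRI, in R.

Most functional connectivity studies analyse group-level networks and
discard subject-specific topography, and almost all of them stop at
node-wise correlations. `connectokit` implements the complementary
programme: map **personalized large-scale functional networks** for
every subject with spatially regularized non-negative matrix
factorization (NMF), then analyse both the node-wise and the
**edge-wise** connectome — edge time series, edge-wise functional
connectivity (eFC), co-fluctuation amplitude (RSS) events, amplitude
transitions, edge communities — together with graph-theoretic network
attributes and a group-comparison statistics layer. It is aimed at
researchers comparing clinical groups (e.g. autism spectrum disorder
and ADHD subtypes against typical development) on individual network
phenotypes.

## The model in brief

Each subject's masked BOLD matrix (voxels × time, rescaled per voxel to
[0, 1]) is factorized as `X ≈ W H` with non-negative time courses `W`
(T × K) and spatial loadings `H` (K × V), minimizing

    ||X − WH||²_F + β tr(H L Hᵀ) + α ||H − H_prior||²_F

where `L` is the voxel-lattice graph Laplacian (spatial smoothness) and
`H_prior` is a group consensus atlas built by spectral clustering of
repeated decompositions — so row *k* of every subject atlas means the
same network. From the subject time courses the package computes:

- **FNC**: K × K Pearson correlations between network time courses;
- **edge time series**: `e_ij(t) = z_i(t)·z_j(t)` for all K(K−1)/2
  pairs, whose time average is exactly the Pearson correlation;
- **eFC**: correlations between edge time series (136 × 136 at K = 17);
- **RSS** amplitude per frame, top/bottom 5% tail amplitudes, and
  B/N/T level-transition counts;
- **graph attributes** of significance-thresholded graphs: Cp, Lp,
  Eglob, Eloc, assortativity, modularity Q, betweenness, degree, and
  small-world γ, λ, σ against degree-preserving nulls;
- **edge communities**: signed spectral modularity for the module
  count, correlation-distance k-means for the partition;
- **statistics**: FD-covaried ANCOVA gates, pairwise post-hoc t-tests
  under pooled BH-FDR, and clinical score correlations.

A synthetic cohort generator (`cohort_design()`, `simulate_cohort()`)
with planted covariance effects, motion traces and clinical scores
makes the full pipeline testable end to end without imaging data.

## Worked example

Simulate two groups of 20 subjects with one planted group difference —
ASD gains +0.4 latent covariance on the network pair (2, 5) — then map
networks and screen all FNC pairs:

```r
library(connectokit)

design <- cohort_design(
  groups = c(TD = 20, ASD = 20), V = 150, K = 6, T_raw = 60,
  fnc_effects = list(list(group = "ASD", pair = c(2, 5), delta = 0.4)),
  seed = 42)
cohort <- simulate_cohort(design)
scans  <- lapply(cohort$scans, drop_initial_volumes, n_drop = 10)

cfg   <- nmf_config(K = 6, repeats = 3, max_iter = 200, seed = 1)
L     <- build_voxel_graph(voxel_grid(design$V))
atlas <- consensus_atlas(group_initialize(scans, cfg, L = L), 6, seed = 1)
fits  <- lapply(scans, personalize, group_atlas = atlas, cfg = cfg, L = L)

reconstruction_accuracy(scans, lapply(fits, `[[`, "tc"),
                        lapply(fits, `[[`, "atlas"), assign_voxels(atlas))
#>  net1  net2  net3  net4  net5  net6
#> 0.901 0.893 0.898 0.899 0.895 0.894

pairs <- edge_index(6)
feats <- t(vapply(fits, function(f) {
  C <- node_fnc(f$tc); C[cbind(pairs[, 1], pairs[, 2])]
}, numeric(nrow(pairs))))
colnames(feats) <- paste0("fnc_", pairs[, 1], "_", pairs[, 2])
screen <- feature_screen(feats, factor(cohort$phenotype$group),
                         cohort$phenotype$mean_fd)
subset(screen$posthoc, significant)
#>   feature group1 group2     t        p    p_fdr significant
#> 1 fnc_2_5    ASD     TD  4.55 5.38e-05 1.61e-04        TRUE
#> 2 fnc_2_6    ASD     TD -2.71 1.01e-02 1.51e-02        TRUE
#> 3 fnc_3_5    ASD     TD -3.46 1.34e-03 2.67e-03        TRUE
#> 4 fnc_3_6    ASD     TD  2.16 3.75e-02 4.03e-02        TRUE
#> 5 fnc_4_6    ASD     TD  2.12 4.03e-02 4.03e-02        TRUE
#> 6 fnc_5_6    ASD     TD  8.67 1.53e-10 9.16e-10        TRUE
```

Reconstruction accuracy is the mean voxelwise correlation between the
original and reconstructed signals per network (~0.9 here; the minimum
reported for real cohorts of this kind is about 0.69). In the screen,
ground-truth networks (2, 5) map to consensus atlas rows (5, 6), so the
strongest hit `fnc_5_6` (t = 8.67) *is* the planted effect recovered
through the full pipeline; the weaker hits reflect the correlated
secondary shifts a planted covariance delta induces after SPD
projection.

Edge-centric analyses for one subject:

```r
ets <- edge_time_series(fits[[1]]$tc)
efc <- edge_fnc(ets)
sw  <- small_world(threshold_significant(efc, ncol(ets$ets)),
                   n_null = 50, seed = 2)
#> gamma 1.84 lambda 1.14 sigma 1.61 (small-world criterion met)

pr <- rss_profile(ets, frac = 0.05)
tail_amplitude(pr, "top");  tail_amplitude(pr, "bottom")
#> 8.97  0.70
count_transitions(pr$labels)
#>     to
#> from B  N T
#>    B 0  3 0
#>    N 3 37 3
#>    T 0  3 0
```

`run_pipeline(pipeline_config(design, out_dir))` chains all stages —
simulate, preprocess, map-networks, connectivity, graph, communities,
stats — writes each stage's tables under `out_dir`, and emits a
manifest with derived per-stage seeds and output checksums; identical
configurations reproduce identical checksums.

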