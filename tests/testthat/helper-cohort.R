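# Shared fixtures. The default-scale netmap run is expensive (minutes),
# so it is computed once per session and reused by every test that
# needs it.

.fixture_env <- new.env(parent = emptyenv())

# default study-scale cohort: V = 2000, K = 17, 20 subjects, seed 42
default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    d <- cohort_design(seed = 42,
                       groups = c(TD = 5, ASD = 5, `ADHD-C` = 5, `ADHD-I` = 5))
    .fixture_env$cohort <- simulate_cohort(d)
  }
  .fixture_env$cohort
}

# full netmap stage on the default cohort (10 consensus repeats)
default_netmap <- function() {
  if (is.null(.fixture_env$netmap)) {
    co <- default_cohort()
    scans <- lapply(co$scans, drop_initial_volumes, n_drop = 10)
    cfg <- nmf_config(K = 17, repeats = 10, seed = 11)
    L <- build_voxel_graph(voxel_grid(co$truth$design$V))
    reps <- group_initialize(scans, cfg, L = L)
    atlas <- consensus_atlas(reps, 17, seed = 11)
    fits <- lapply(scans, personalize, group_atlas = atlas, cfg = cfg, L = L)
    .fixture_env$netmap <- list(scans = scans, atlas = atlas, fits = fits,
                                labels = assign_voxels(atlas),
                                truth = co$truth)
  }
  .fixture_env$netmap
}

# small fast cohort for contract-level tests
small_cohort <- function(seed = 7, n_per_group = 3, V = 125, K = 4,
                         T_raw = 60, fnc_effects = list()) {
  d <- cohort_design(groups = c(TD = n_per_group, ASD = n_per_group),
                     V = V, K = K, T_raw = T_raw, n_communities = 3,
                     fnc_effects = fnc_effects, seed = seed)
  simulate_cohort(d)
}
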