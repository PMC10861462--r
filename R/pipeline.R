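#' Pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed; each
#' stage derives its own seed deterministically from the global seed and
#' the stage name, so reruns with the same configuration reproduce
#' identical outputs.
#'
#' @param design a \code{\link{cohort_design}} for the simulate stage.
#' @param out_dir output directory (created if missing; its parent must
#'   exist).
#' @param n_drop leading volumes to drop.
#' @param fd_thresh scrubbing / exclusion FD threshold (mm).
#' @param band band-pass edges in Hz.
#' @param nmf an \code{\link{nmf_config}}.
#' @param frac RSS tail fraction.
#' @param alpha graph threshold / ANCOVA gate level.
#' @param q FDR level.
#' @param n_null small-world null-ensemble size.
#' @param seed global integer seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(design, out_dir, n_drop = 10L, fd_thresh = 0.5,
                            band = c(0.01, 0.1), nmf = nmf_config(K = design$K),
                            frac = 0.05, alpha = 0.05, q = 0.05,
                            n_null = 100L, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"), inherits(nmf, "nmf_config"))
  structure(list(design = design, out_dir = out_dir, n_drop = n_drop,
                 fd_thresh = fd_thresh, band = band, nmf = nmf, frac = frac,
                 alpha = alpha, q = q, n_null = as.integer(n_null),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-stage seed below 2^31
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(global_seed) * 7919 + h * 104729) %% 2147483647)
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, map-networks, connectivity, graph,
#' communities and stats in order, persisting each stage's outputs as
#' TSV/JSON under \code{out_dir} and returning a manifest (stage list,
#' derived seeds, output file checksums). Any stage failure aborts with
#' the stage name; outputs of completed stages are kept on disk.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return The manifest (also written to \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(dirname(config$out_dir)))
    stop("missing output parent directory: ", dirname(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE)
  out <- config$out_dir
  stages <- c("simulate", "preprocess", "map-networks", "connectivity",
              "graph", "communities", "stats")
  seeds <- vapply(stages, function(s) stage_seed(config$seed, s), integer(1))
  files <- character(0)
  stage_env <- new.env()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  run_stage("simulate", function() {
    d <- config$design
    d$seed <- seeds[["simulate"]]
    cohort <- simulate_cohort(d)
    stage_env$cohort <- cohort
    .write_tsv(cohort$phenotype, file.path(out, "phenotype.tsv"))
    files <<- c(files, "phenotype.tsv")
  })

  # --- preprocess -------------------------------------------------------
  run_stage("preprocess", function() {
    cohort <- stage_env$cohort
    pp <- lapply(cohort$scans, preprocess_scan, n_drop = config$n_drop,
                 low_hz = config$band[1], high_hz = config$band[2],
                 fd_thresh = config$fd_thresh)
    ex <- exclude_subjects(pp, max_mean_fd = config$fd_thresh)
    stage_env$scans <- ex$scans
    .write_tsv(ex$report, file.path(out, "exclusions.tsv"))
    files <<- c(files, "exclusions.tsv")
  })

  # --- map-networks -----------------------------------------------------
  run_stage("map-networks", function() {
    scans <- stage_env$scans
    cfg <- config$nmf
    cfg$seed <- seeds[["map-networks"]]
    L <- build_voxel_graph(voxel_grid(nrow(scans[[1]]$signal)))
    reps <- group_initialize(scans, cfg, L = L)
    atlas <- consensus_atlas(reps, cfg$K, seed = cfg$seed)
    fits <- lapply(scans, personalize, group_atlas = atlas, cfg = cfg, L = L)
    stage_env$atlas <- atlas
    stage_env$fits <- fits
    labels <- assign_voxels(atlas)
    acc <- reconstruction_accuracy(scans, lapply(fits, `[[`, "tc"),
                                   lapply(fits, `[[`, "atlas"), labels)
    .write_tsv(data.frame(network = names(acc), accuracy = acc),
               file.path(out, "reconstruction_accuracy.tsv"))
    .write_tsv(as.data.frame(atlas), file.path(out, "group_atlas.tsv"))
    files <<- c(files, "reconstruction_accuracy.tsv", "group_atlas.tsv")
  })

  # --- connectivity -----------------------------------------------------
  run_stage("connectivity", function() {
    fits <- stage_env$fits
    conn <- lapply(fits, function(f) {
      ets <- edge_time_series(f$tc)
      prof <- rss_profile(ets, config$frac)
      list(fnc = node_fnc(f$tc), ets = ets, efc = edge_fnc(ets),
           rss = prof, transitions = count_transitions(prof$labels),
           top = tail_amplitude(prof, "top"),
           bottom = tail_amplitude(prof, "bottom"))
    })
    stage_env$conn <- conn
    amp <- data.frame(
      subject_id = vapply(stage_env$scans, `[[`, "", "subject_id"),
      top = vapply(conn, `[[`, 0, "top"),
      bottom = vapply(conn, `[[`, 0, "bottom"))
    .write_tsv(amp, file.path(out, "rss_amplitude.tsv"))
    files <<- c(files, "rss_amplitude.tsv")
  })

  # --- graph ------------------------------------------------------------
  run_stage("graph", function() {
    conn <- stage_env$conn
    Tn <- ncol(conn[[1]]$ets$ets)
    gseed <- seeds[["graph"]]
    gm <- lapply(seq_along(conn), function(i) {
      ga <- graph_attributes(conn[[i]]$fnc, Tn, alpha = config$alpha,
                             n_null = config$n_null, seed = gseed + i)
      c(list(subject_id = stage_env$scans[[i]]$subject_id),
        ga$global, gamma = ga$small_world$gamma,
        lambda = ga$small_world$lambda, sigma = ga$small_world$sigma)
    })
    gdf <- do.call(rbind, lapply(gm, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
    stage_env$graph <- gdf
    .write_tsv(gdf, file.path(out, "graph_metrics_node.tsv"))
    files <<- c(files, "graph_metrics_node.tsv")
  })

  # --- communities ------------------------------------------------------
  run_stage("communities", function() {
    conn <- stage_env$conn
    efc_group <- Reduce(`+`, lapply(conn, `[[`, "efc")) / length(conn)
    k <- optimal_module_count(efc_group)$k
    comm <- edge_kmeans(efc_group, k, seed = seeds[["communities"]],
                        n_restarts = 10)
    pairs <- conn[[1]]$ets$pairs
    counts <- community_network_counts(comm$labels, pairs,
                                       K = config$design$K)
    stage_env$communities <- comm
    lab_df <- data.frame(edge = seq_along(comm$labels),
                         i = pairs[, 1], j = pairs[, 2],
                         community = comm$labels)
    .write_tsv(lab_df, file.path(out, "edge_communities.tsv"))
    .write_tsv(as.data.frame(counts), file.path(out, "community_counts.tsv"))
    files <<- c(files, "edge_communities.tsv", "community_counts.tsv")
  })

  # --- stats ------------------------------------------------------------
  run_stage("stats", function() {
    conn <- stage_env$conn
    scans <- stage_env$scans
    pairs <- conn[[1]]$ets$pairs
    feats <- t(vapply(conn, function(x)
      x$fnc[cbind(pairs[, 1], pairs[, 2])], numeric(nrow(pairs))))
    colnames(feats) <- paste0("fnc_", pairs[, 1], "_", pairs[, 2])
    grp <- factor(vapply(scans, `[[`, "", "group"))
    fd <- vapply(scans, `[[`, 0, "mean_fd")
    scr <- feature_screen(feats, grp, fd, alpha = config$alpha, q = config$q)
    stage_env$screen <- scr
    .write_tsv(scr$omnibus, file.path(out, "fnc_omnibus.tsv"))
    .write_tsv(scr$posthoc, file.path(out, "fnc_posthoc.tsv"))
    files <<- c(files, "fnc_omnibus.tsv", "fnc_posthoc.tsv")
  })

  paths <- file.path(out, files)
  manifest <- list(stages = stages, seeds = as.list(seeds),
                   n_subjects = length(stage_env$scans),
                   outputs = files,
                   checksums = as.list(setNames(unname(tools::md5sum(paths)),
                                                files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
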