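#' Describe a synthetic resting-state cohort
#'
#' Collects the generative parameters of a synthetic multi-subject
#' resting-state cohort: group sizes, voxel and network counts, scan
#' length, planted group differences in the latent network covariance,
#' per-group head-motion levels and clinical scores tied to ground-truth
#' network metrics. The defaults emulate a four-group neurodevelopmental
#' study (typically developing controls, ASD, ADHD-combined and
#' ADHD-inattentive) scanned for 180 frames at TR = 2 s and mapped onto
#' K = 17 latent networks, at a desk-scale voxel count.
#'
#' @param groups named integer vector: subjects per group (>= 2 each).
#' @param V number of voxels (>= K).
#' @param K number of latent networks.
#' @param T_raw frames per scan before volume dropping.
#' @param TR repetition time in seconds.
#' @param fnc_effects list of planted covariance effects, each a list with
#'   elements \code{group}, \code{pair = c(i, j)} and \code{delta}
#'   (0 < |delta| < 1), added to that group's latent covariance.
#' @param motion_level named numeric: target mean framewise displacement
#'   (mm) per group. Defaults follow typical paediatric resting-state
#'   values with elevated motion in the clinical groups.
#' @param clinical_links list of score generators, each a list with
#'   elements \code{score} (column name), \code{metric} (either
#'   \code{"fnc:i:j"} for the subject's true latent correlation of
#'   networks i,j, or \code{"mean_fd"}) and \code{r} (target correlation).
#' @param snr per-voxel signal-to-noise variance ratio.
#' @param ar_coef AR(1) coefficient of the latent network series
#'   (BOLD-like temporal smoothness).
#' @param spatial_sd standard deviation of the per-subject additive
#'   perturbation of the spatial loadings.
#' @param cov_jitter_sd standard deviation of the per-subject jitter on
#'   latent covariance off-diagonals (gives within-group variability).
#' @param n_communities number of planted edge communities recorded in
#'   the ground truth.
#' @param seed integer master seed.
#'
#' @return An object of class \code{cohort_design}.
#' @export
cohort_design <- function(groups = c(TD = 15L, ASD = 15L, `ADHD-C` = 15L, `ADHD-I` = 15L),
                          V = 2000L, K = 17L, T_raw = 180L, TR = 2,
                          fnc_effects = list(),
                          motion_level = c(TD = 0.13, ASD = 0.18,
                                           `ADHD-C` = 0.22, `ADHD-I` = 0.33),
                          clinical_links = list(),
                          snr = 4, ar_coef = 0.3,
                          spatial_sd = 0.05, cov_jitter_sd = 0.05,
                          n_communities = 8L,
                          seed = 1L) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  if (any(groups < 2)) stop("each group needs at least 2 subjects")
  if (V < K) stop("V must be >= K")
  for (eff in fnc_effects) {
    d <- eff$delta
    if (!(abs(d) > 0 && abs(d) < 1))
      stop("covariance delta must satisfy 0 < |delta| < 1")
    if (!eff$group %in% names(groups)) stop("unknown group in fnc_effects: ", eff$group)
    p <- eff$pair
    if (length(p) != 2 || any(p < 1) || any(p > K) || p[1] == p[2])
      stop("fnc_effects pair must be two distinct network indices in 1..K")
  }
  ml <- motion_level[names(groups)]
  if (any(is.na(ml))) stop("motion_level must name every group")
  structure(list(groups = groups, V = as.integer(V), K = as.integer(K),
                 T_raw = as.integer(T_raw), TR = TR,
                 fnc_effects = fnc_effects, motion_level = ml,
                 clinical_links = clinical_links, snr = snr,
                 ar_coef = ar_coef, spatial_sd = spatial_sd,
                 cov_jitter_sd = cov_jitter_sd,
                 n_communities = as.integer(n_communities),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Voxel lattice coordinates
#'
#' Raster-fills a near-cubic integer lattice with V voxels; the
#' coordinate table feeds \code{\link{build_voxel_graph}}.
#'
#' @param V number of voxels.
#' @return V x 3 integer coordinate matrix.
#' @export
voxel_grid <- function(V) {
  side <- ceiling(V^(1 / 3))
  nz <- ceiling(V / side^2)
  g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(nz))
  as.matrix(g[seq_len(V), , drop = FALSE])
}

# project a symmetric matrix to the SPD cone by eigenvalue clipping
spd_project <- function(S, floor = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= floor) return(S)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

#' Build the ground truth of a synthetic cohort
#'
#' Constructs the generative objects every simulated subject is drawn
#' from: a K x V non-negative spatial atlas whose dominant loadings tile
#' the voxel lattice into K contiguous blocks, one latent K x K
#' covariance per group (shared base covariance plus the planted deltas,
#' projected back to SPD), a planted partition of the K(K-1)/2 network
#' pairs into edge communities, and the clinical-score coefficients.
#'
#' @param design a \code{\link{cohort_design}}.
#' @return A list of class \code{ground_truth} with elements
#'   \code{atlas} (K x V), \code{coords} (V x 3 lattice coordinates),
#'   \code{base_cov}, \code{group_cov} (named list of K x K SPD
#'   matrices), \code{edge_partition} (length-E community labels) and
#'   \code{design}.
#' @export
make_ground_truth <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  K <- design$K; V <- design$V

  # atlas: contiguous index blocks, Gaussian falloff from each block centre
  bounds <- round(seq(0, V, length.out = K + 1))
  centers <- (bounds[-1] + bounds[-(K + 1)] + 1) / 2
  width <- V / K
  idx <- seq_len(V)
  atlas <- t(vapply(seq_len(K), function(k) {
    exp(-((idx - centers[k]) / (width / 2))^2) + 0.01
  }, numeric(V)))
  atlas <- atlas / apply(atlas, 1, max)

  # base latent covariance: equicorrelation 0.2, then planted group deltas
  base <- matrix(0.2, K, K); diag(base) <- 1
  group_cov <- lapply(names(design$groups), function(g) {
    S <- base
    for (eff in design$fnc_effects) {
      if (eff$group == g) {
        i <- eff$pair[1]; j <- eff$pair[2]
        S[i, j] <- S[i, j] + eff$delta
        S[j, i] <- S[i, j]
      }
    }
    Sp <- spd_project(S)
    if (max(abs(Sp - S)) > 0.05)
      stop("planted covariance deltas make the matrix non-SPD for group ", g)
    Sp
  })
  names(group_cov) <- names(design$groups)

  E <- K * (K - 1) / 2
  kc <- min(design$n_communities, E)
  edge_partition <- as.integer(cut(seq_len(E), breaks = kc, labels = FALSE))

  structure(list(atlas = atlas, coords = voxel_grid(V), base_cov = base,
                 group_cov = group_cov, edge_partition = edge_partition,
                 design = design),
            class = "ground_truth")
}

# chol-based multivariate normal draws, n x K
rmvn <- function(n, Sigma) {
  R <- chol(Sigma)
  matrix(rnorm(n * ncol(Sigma)), n) %*% R
}

#' Simulate one subject's scan
#'
#' Draws the subject's latent network time series as a stationary AR(1)
#' process with the group covariance (jittered per subject), forms the
#' voxel signals as \code{t(loadings) \%*\% latent} plus i.i.d. Gaussian
#' noise at the design SNR, and adds a cumulative-sum random-walk motion
#' trace scaled to the group motion level (rotations in radians).
#'
#' @param truth a \code{\link{make_ground_truth}} result.
#' @param group group label (must exist in the design).
#' @param subject_seed integer seed for this subject.
#' @param subject_id optional id string.
#' @param T_frames optional override of the number of frames.
#' @return An object of class \code{subject_scan}: list with
#'   \code{signal} (V x T), \code{motion} (T x 6), \code{tr},
#'   \code{subject_id}, \code{group}, plus ground-truth fields
#'   \code{true_loadings} (K x V), \code{true_cov} (K x K) and
#'   \code{true_latent} (T x K) for parameter-recovery checks.
#' @export
simulate_subject <- function(truth, group, subject_seed,
                             subject_id = paste0("sub-", subject_seed),
                             T_frames = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- truth$design
  if (!group %in% names(d$groups)) stop("unknown group label: ", group)
  set.seed(as.integer(subject_seed))
  K <- d$K; V <- d$V
  Tn <- if (is.null(T_frames)) d$T_raw else as.integer(T_frames)

  # subject-specific latent covariance: group cov + symmetric jitter
  S <- truth$group_cov[[group]]
  if (d$cov_jitter_sd > 0) {
    J <- matrix(rnorm(K * K, sd = d$cov_jitter_sd), K)
    J <- (J + t(J)) / 2; diag(J) <- 0
    S <- spd_project(S + J)
  }

  # stationary AR(1) latent series with innovation scaling sqrt(1 - phi^2)
  phi <- d$ar_coef
  eps <- rmvn(Tn, S)
  z <- matrix(0, Tn, K)
  z[1, ] <- eps[1, ]
  if (Tn > 1) {
    w <- sqrt(1 - phi^2)
    for (t in 2:Tn) z[t, ] <- phi * z[t - 1, ] + w * eps[t, ]
  }

  # subject loadings: perturbed atlas, clipped non-negative
  H <- truth$atlas
  if (d$spatial_sd > 0) {
    H <- pmax(H + matrix(rnorm(K * V, sd = d$spatial_sd), K), 0)
    zr <- rowSums(H) == 0
    if (any(zr)) H[zr, ] <- truth$atlas[zr, ]
  }

  X <- t(H) %*% t(z)                         # V x T
  if (is.finite(d$snr)) {
    sds <- apply(X, 1, sd) / sqrt(d$snr)
    X <- X + matrix(rnorm(V * Tn), V) * sds
  }

  # motion: Gaussian-step random walk; E|step| = s*sqrt(2/pi), FD sums six
  # |delta| terms (rotation steps are 1/50 of translation, FD radius 50 mm).
  # The group level is a mean: subjects draw a lognormal multiplier so
  # within-group FD spreads like real cohorts instead of collapsing onto
  # the group mean (which would make FD collinear with group).
  lvl <- d$motion_level[[group]] * exp(rnorm(1, -0.125, 0.5))
  s_t <- lvl / (6 * sqrt(2 / pi))
  steps <- cbind(matrix(rnorm(Tn * 3, sd = s_t), Tn),
                 matrix(rnorm(Tn * 3, sd = s_t / 50), Tn))
  steps[1, ] <- 0
  motion <- apply(steps, 2, cumsum)
  if (Tn == 1) motion <- matrix(motion, 1)

  structure(list(signal = X, motion = motion, tr = d$TR,
                 subject_id = subject_id, group = group,
                 true_loadings = H, true_cov = S, true_latent = z),
            class = "subject_scan")
}

#' Simulate a full cohort
#'
#' Generates one scan per subject together with a phenotype table
#' (group, age, sex, mean framewise displacement and any clinical scores
#' declared in the design). Clinical scores are generated post hoc from
#' the subjects' ground-truth metrics so that their correlation with the
#' linked metric targets the requested value.
#'
#' @param design a \code{\link{cohort_design}}.
#' @return List with \code{scans} (list of \code{subject_scan}),
#'   \code{phenotype} (data.frame) and \code{truth}
#'   (\code{\link{make_ground_truth}} output).
#' @export
simulate_cohort <- function(design) {
  truth <- make_ground_truth(design)
  n <- sum(design$groups)
  set.seed(design$seed + 1L)
  sub_seeds <- sample.int(2147483646L, n)
  ages <- pmax(6, rnorm(n, mean = 11.5, sd = 2.5))
  sexes <- ifelse(runif(n) < 0.83, "M", "F")

  glabels <- rep(names(design$groups), times = design$groups)
  scans <- vector("list", n)
  mean_fd <- numeric(n)
  ids <- sprintf("sub-%03d", seq_len(n))
  for (i in seq_len(n)) {
    scans[[i]] <- simulate_subject(truth, glabels[i], sub_seeds[i],
                                   subject_id = ids[i])
    mean_fd[i] <- compute_fd(scans[[i]]$motion)$mean_fd
  }

  pheno <- data.frame(subject_id = ids, group = glabels, age = ages,
                      sex = sexes, mean_fd = mean_fd,
                      stringsAsFactors = FALSE)

  # clinical scores: score = r * z(metric) + sqrt(1-r^2) * noise
  if (length(design$clinical_links) > 0) {
    set.seed(design$seed + 2L)
    for (link in design$clinical_links) {
      m <- .link_metric(link$metric, scans, pheno)
      zm <- as.numeric(scale(m))
      r <- link$r
      pheno[[link$score]] <- r * zm + sqrt(1 - r^2) * rnorm(n)
    }
  }
  list(scans = scans, phenotype = pheno, truth = truth)
}

.link_metric <- function(metric, scans, pheno) {
  if (identical(metric, "mean_fd")) return(pheno$mean_fd)
  parts <- strsplit(metric, ":", fixed = TRUE)[[1]]
  if (length(parts) == 3 && parts[1] == "fnc") {
    i <- as.integer(parts[2]); j <- as.integer(parts[3])
    return(vapply(scans, function(s) {
      C <- s$true_cov
      C[i, j] / sqrt(C[i, i] * C[j, j])
    }, numeric(1)))
  }
  stop("unknown clinical link metric: ", metric)
}

#' Simulate edge time series with planted community structure
#'
#' Generates an E x T matrix of edge-like co-fluctuation series in which
#' edges of the same planted community share a latent signal, so that
#' their edge-wise correlation matrix (eFC) has block structure. Used to
#' validate the edge-community detection operations against a known
#' partition.
#'
#' @param partition integer vector of community labels, one per edge.
#' @param T_frames number of frames.
#' @param strength fraction of each row's variance carried by its
#'   community signal (within-community correlation).
#' @param seed integer seed.
#' @return E x T matrix.
#' @export
simulate_edge_series <- function(partition, T_frames = 170, strength = 0.5,
                                 seed = 1L) {
  stopifnot(strength > 0, strength < 1)
  set.seed(as.integer(seed))
  E <- length(partition)
  k <- max(partition)
  # independent community signals: distinct co-fluctuation modes with
  # block-diagonal expected eFC structure
  S <- matrix(rnorm(k * T_frames), k)
  sqrt(strength) * S[partition, , drop = FALSE] +
    sqrt(1 - strength) * matrix(rnorm(E * T_frames), E)
}
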