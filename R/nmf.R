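#' NMF configuration
#'
#' Parameters of the spatially regularized NMF decomposition. The
#' spatial weight \code{beta} and prior-adherence weight \code{alpha}
#' default to scale-adaptive values proportional to the data energy
#' (\code{1e-3 * ||X||_F^2 / V} and \code{1e-1 * ||X||_F^2 / V}
#' respectively) when left \code{NULL}; the spatial weight is kept an
#' order of magnitude below the prior weight because a heavier
#' Laplacian penalty visibly blurs adjacent networks into each other.
#'
#' @param K number of networks.
#' @param beta spatial (graph-Laplacian) regularization weight, or NULL
#'   for the scale-adaptive default.
#' @param alpha prior-adherence weight, or NULL for the scale-adaptive
#'   default (only used when a prior is supplied).
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative objective-change convergence tolerance.
#' @param repeats number of random-restart decompositions in the group
#'   initialization stage.
#' @param seed integer seed for random initializations.
#' @return An object of class \code{nmf_config}.
#' @export
nmf_config <- function(K = 17L, beta = NULL, alpha = NULL, max_iter = 500L,
                       tol = 1e-5, repeats = 50L, seed = 1L) {
  stopifnot(K >= 2, is.null(beta) || beta >= 0, is.null(alpha) || alpha >= 0)
  structure(list(K = as.integer(K), beta = beta, alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "nmf_config")
}

#' Rescale voxel time series to [0, 1]
#'
#' Per voxel: shift by the minimum so all values are non-negative, then
#' divide by the resulting maximum. Constant voxels map to all zeros.
#'
#' @param signal V x T matrix.
#' @return V x T matrix in [0, 1].
#' @export
normalize_nonnegative <- function(signal) {
  mn <- apply(signal, 1, min)
  X <- signal - mn
  mx <- apply(X, 1, max)
  mx[mx == 0] <- 1
  X / mx
}

#' Voxel-lattice graph Laplacian
#'
#' Builds the sparse combinatorial Laplacian L = D - A of the voxel
#' adjacency graph on integer lattice coordinates, for the standard 6-,
#' 18- or 26-neighbourhoods.
#'
#' @param coords V x 3 integer lattice coordinates.
#' @param neighborhood 6, 18 or 26.
#' @return Sparse symmetric V x V Laplacian (Matrix package).
#' @export
build_voxel_graph <- function(coords, neighborhood = 6) {
  stopifnot(neighborhood %in% c(6, 18, 26))
  coords <- as.matrix(coords)
  V <- nrow(coords)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(offs))
  offs <- offs[l1 > 0 & l1 <= switch(as.character(neighborhood),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  # integer key per coordinate for O(1) neighbour lookup
  span <- apply(coords, 2, max) + 2
  key <- function(m) (m[, 1] + 1) + span[1] * ((m[, 2] + 1) + span[2] * (m[, 3] + 1))
  lookup <- new.env(hash = TRUE, size = V)
  kc <- key(coords)
  for (v in seq_len(V)) assign(as.character(kc[v]), v, envir = lookup)
  ii <- integer(0); jj <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[o, ], "+")
    kn <- key(nb)
    hit <- vapply(as.character(kn), function(k) {
      if (exists(k, envir = lookup, inherits = FALSE))
        get(k, envir = lookup) else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
    ok <- which(!is.na(hit))
    ii <- c(ii, ok); jj <- c(jj, hit[ok])
  }
  A <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(V, V))
  A <- (A + Matrix::t(A)) / 2          # symmetrize; entries stay 1
  A@x[] <- 1
  Diagonal(x = Matrix::rowSums(A)) - A
}

# internal: regularized NMF objective, recomputed from its definition
.nmf_objective <- function(Xt, W, H, beta, alpha, L, P, normX2 = NULL,
                           XtHt = NULL) {
  if (is.null(normX2)) normX2 <- sum(Xt^2)
  fit <- normX2 - 2 * sum(crossprod(W, Xt) * H) +
    sum(crossprod(W) * tcrossprod(H))
  obj <- fit
  if (beta > 0 && !is.null(L)) obj <- obj + beta * sum(H * as.matrix(H %*% L))
  if (alpha > 0 && !is.null(P)) obj <- obj + alpha * sum((H - P)^2)
  obj
}

#' Spatially regularized NMF by multiplicative updates
#'
#' Minimizes
#' \deqn{\|X - WH\|_F^2 + \beta\,\mathrm{tr}(H L H^T) + \alpha \|H - H_{prior}\|_F^2}
#' over non-negative factors W (time courses) and H (spatial loadings),
#' using Lee-Seung multiplicative updates extended with the graph and
#' prior penalties. The input is the V x T voxel matrix; it is
#' transposed internally so that W is T x K and H is K x V. The recorded
#' objective trace is non-increasing.
#'
#' @param X V x T non-negative matrix.
#' @param cfg an \code{\link{nmf_config}}.
#' @param W_init,H_init optional initial factors (T x K, K x V). When
#'   missing, random non-negative initialization seeded by
#'   \code{cfg$seed}.
#' @param H_prior optional K x V prior atlas; activates the alpha term.
#' @param L optional sparse V x V Laplacian; activates the beta term.
#' @return List with \code{W} (T x K), \code{H} (K x V, rows
#'   max-normalized with W rescaled inversely) and \code{objective}
#'   (per-iteration trace, including the value at initialization).
#' @export
nmf_decompose <- function(X, cfg, W_init = NULL, H_init = NULL,
                          H_prior = NULL, L = NULL) {
  if (min(X) < 0) stop("X must be non-negative")
  V <- nrow(X); Tn <- ncol(X); K <- cfg$K
  Xt <- t(X)
  normX2 <- sum(Xt^2)
  beta <- if (is.null(cfg$beta)) 1e-3 * normX2 / V else cfg$beta
  alpha <- if (is.null(H_prior)) 0
           else if (is.null(cfg$alpha)) 1e-1 * normX2 / V else cfg$alpha
  if (!is.null(L)) {
    if (nrow(L) != V) stop("Laplacian dimension mismatch")
    A <- -L; diag(A) <- 0
    Dg <- Matrix::diag(L)
  } else beta <- 0

  if (is.null(W_init) || is.null(H_init)) set.seed(cfg$seed)
  W <- if (is.null(W_init)) matrix(runif(Tn * K), Tn) else W_init
  H <- if (is.null(H_init)) matrix(runif(K * V), K) else H_init
  P <- H_prior

  obj <- numeric(cfg$max_iter + 1)
  obj[1] <- .nmf_objective(Xt, W, H, beta, alpha, L, P, normX2)
  n_it <- 0
  for (it in seq_len(cfg$max_iter)) {
    # W update (H fixed)
    HHt <- tcrossprod(H)
    W <- W * (Xt %*% t(H)) / (W %*% HHt + .EPS)
    # H update (W fixed)
    WtX <- crossprod(W, Xt)
    WtW <- crossprod(W)
    num <- WtX
    den <- WtW %*% H
    if (beta > 0) {
      num <- num + beta * as.matrix(H %*% A)
      den <- den + beta * sweep(H, 2, Dg, "*")
    }
    if (alpha > 0) {
      num <- num + alpha * P
      den <- den + alpha * H
    }
    H <- H * num / (den + .EPS)
    n_it <- it
    obj[it + 1] <- {
      fit <- normX2 - 2 * sum(WtX * H) + sum(WtW * tcrossprod(H))
      o <- fit
      if (beta > 0) o <- o + beta * sum(H * as.matrix(H %*% L))
      if (alpha > 0) o <- o + alpha * sum((H - P)^2)
      o
    }
    if (abs(obj[it] - obj[it + 1]) < cfg$tol * max(obj[it], .EPS)) break
  }
  obj <- obj[seq_len(n_it + 1)]

  # resolve scale indeterminacy: max-normalize H rows, rescale W columns
  s <- apply(H, 1, max)
  s[s == 0] <- 1
  H <- H / s
  W <- sweep(W, 2, s, "*")
  list(W = W, H = H, objective = obj)
}

#' Group network initialization
#'
#' Concatenates the subjects' normalized voxel time series along time
#' (sampling at most \code{max_subjects} subjects without replacement
#' when more are available) and decomposes the pooled matrix
#' \code{repeats} times with fresh random non-negative initializations.
#'
#' @param scans list of \code{subject_scan} (all with equal V).
#' @param cfg an \code{\link{nmf_config}}.
#' @param L optional voxel-graph Laplacian.
#' @param max_subjects subject subsample cap (default 50).
#' @return List of K x V atlases, one per repeat.
#' @export
group_initialize <- function(scans, cfg, L = NULL, max_subjects = 50L) {
  if (length(scans) < 2) stop("need at least 2 scans")
  Vs <- vapply(scans, function(s) nrow(s$signal), integer(1))
  if (length(unique(Vs)) != 1) stop("subjects have mismatched voxel counts")
  set.seed(cfg$seed)
  use <- if (length(scans) > max_subjects)
    sort(sample.int(length(scans), max_subjects)) else seq_along(scans)
  Xcat <- do.call(cbind, lapply(scans[use], function(s)
    normalize_nonnegative(s$signal)))
  out <- lapply(seq_len(cfg$repeats), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    nmf_decompose(Xcat, cfg_r, L = L)$H
  })
  attr(out, "T_concat") <- ncol(Xcat)
  out
}

# Ng-Jordan-Weiss spectral clustering on a similarity matrix
.spectral_cluster <- function(S, k, seed, retries = 5) {
  S[is.na(S)] <- 0
  diag(S) <- 1
  d <- pmax(rowSums(S), .EPS)
  Ln <- S / sqrt(outer(d, d))
  ev <- eigen(Ln, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2)); nrm[nrm == 0] <- 1
  U <- U / nrm
  for (r in seq_len(retries)) {
    set.seed(seed + r - 1)
    km <- tryCatch(kmeans(U, centers = k, nstart = 10, iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) return(km$cluster)
  }
  stop("spectral clustering failed to produce ", k, " non-empty clusters")
}

#' Consensus atlas from repeated decompositions
#'
#' Pools the rows of all repeat atlases (repeats x K rows of length V),
#' clusters them into K groups by spectral clustering on their pairwise
#' correlation similarity, and returns the per-cluster mean rows,
#' max-normalized, as the consensus group atlas.
#'
#' @param atlases list of K x V atlases (equal dimensions).
#' @param K number of networks.
#' @param seed clustering seed.
#' @return K x V consensus atlas; rows ordered by first appearance of
#'   each cluster among the pooled rows.
#' @export
consensus_atlas <- function(atlases, K, seed = 1L) {
  dims <- vapply(atlases, dim, integer(2))
  if (any(dims[1, ] != K) || length(unique(dims[2, ])) != 1)
    stop("atlases must all be K x V with equal V")
  pool <- do.call(rbind, atlases)
  S <- (cor(t(pool)) + 1) / 2
  cl <- .spectral_cluster(S, K, seed)
  order_first <- unique(cl)
  cons <- t(vapply(order_first, function(c)
    colMeans(pool[cl == c, , drop = FALSE]), numeric(ncol(pool))))
  mx <- apply(cons, 1, max); mx[mx == 0] <- 1
  cons / mx
}

#' Personalized network decomposition
#'
#' Decomposes one subject's normalized voxel matrix with the group atlas
#' as both the initialization and the prior anchor of the spatial
#' loadings, so that row k of the subject atlas corresponds to row k of
#' the group atlas without re-matching.
#'
#' @param scan a \code{subject_scan}.
#' @param group_atlas K x V consensus atlas.
#' @param cfg an \code{\link{nmf_config}}.
#' @param L optional voxel-graph Laplacian.
#' @return List with \code{tc} (T x K network time courses W),
#'   \code{atlas} (K x V subject loadings H) and \code{objective}.
#' @export
personalize <- function(scan, group_atlas, cfg, L = NULL) {
  Xn <- normalize_nonnegative(scan$signal)
  if (ncol(group_atlas) != nrow(Xn)) stop("atlas / scan voxel mismatch")
  Xt <- t(Xn)
  W0 <- pmax(Xt %*% t(group_atlas), 0) + .EPS
  W0 <- W0 / max(W0)
  fit <- nmf_decompose(Xn, cfg, W_init = W0, H_init = group_atlas,
                       H_prior = group_atlas, L = L)
  list(tc = fit$W, atlas = fit$H, objective = fit$objective)
}

#' Hard voxel-to-network assignment
#'
#' Assigns each voxel to the network with the maximum loading; ties go
#' to the lowest network index.
#'
#' @param atlas K x V loading matrix.
#' @return Integer vector of length V.
#' @export
assign_voxels <- function(atlas) {
  max.col(t(atlas), ties.method = "first")
}

# correlation between matching rows of two matrices
.row_cors <- function(A, B) {
  Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
  num <- rowSums(Ac * Bc)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-network reconstruction accuracy
#'
#' For every subject and voxel, the Pearson correlation between the
#' normalized original series and the NMF reconstruction (WH); voxelwise
#' correlations are averaged over all voxels carrying each network label
#' and over subjects. Constant voxels (undefined correlation) are
#' excluded from the averages.
#'
#' @param scans list of \code{subject_scan}.
#' @param tcs list of T x K time-course matrices (one per subject).
#' @param atlases list of K x V subject atlases.
#' @param labels integer vector of voxel network labels (length V).
#' @return Named numeric vector of length K: mean correlation per
#'   network.
#' @export
reconstruction_accuracy <- function(scans, tcs, atlases, labels) {
  K <- nrow(atlases[[1]])
  acc_sum <- numeric(K); acc_n <- numeric(K)
  for (s in seq_along(scans)) {
    Xn <- normalize_nonnegative(scans[[s]]$signal)
    R <- t(tcs[[s]] %*% atlases[[s]])          # V x T
    r <- .row_cors(Xn, R)
    ok <- !is.na(r)
    for (k in seq_len(K)) {
      sel <- ok & labels == k
      acc_sum[k] <- acc_sum[k] + sum(r[sel])
      acc_n[k] <- acc_n[k] + sum(sel)
    }
  }
  setNames(acc_sum / pmax(acc_n, 1), paste0("net", seq_len(K)))
}

#' Inter-subject network variability (MAD)
#'
#' Median absolute deviation, across subjects, of each voxel's loading
#' on each network; the per-voxel map averages the MAD over the K
#' networks, and the scalar summary averages the map over voxels.
#'
#' @param atlases list of K x V subject atlases.
#' @return List with \code{mad} (K x V), \code{voxel_map} (length V) and
#'   \code{summary} (scalar).
#' @export
network_variability <- function(atlases) {
  K <- nrow(atlases[[1]]); V <- ncol(atlases[[1]])
  arr <- array(unlist(atlases), dim = c(K, V, length(atlases)))
  med <- apply(arr, c(1, 2), median)
  madm <- apply(abs(arr - as.vector(med)), c(1, 2), median)
  voxel_map <- colMeans(madm)
  list(mad = madm, voxel_map = voxel_map, summary = mean(voxel_map))
}

#' Name networks by reference-atlas overlap
#'
#' Names each network after the reference label whose voxel set has the
#' highest Dice overlap with the network's assigned voxels. Networks
#' sharing a winning label are disambiguated with suffixes -1, -2, ...
#' in order of decreasing network mass (total loading).
#'
#' @param atlas K x V loading matrix.
#' @param reference_labels character vector of length V of canonical
#'   names.
#' @return Character vector of length K: one name per network.
#' @export
label_networks <- function(atlas, reference_labels) {
  K <- nrow(atlas)
  assign <- assign_voxels(atlas)
  refs <- unique(reference_labels)
  best <- character(K)
  for (k in seq_len(K)) {
    a <- assign == k
    dice <- vapply(refs, function(rl) {
      b <- reference_labels == rl
      2 * sum(a & b) / max(sum(a) + sum(b), 1)
    }, numeric(1))
    best[k] <- refs[which.max(dice)]
  }
  mass <- rowSums(atlas)
  out <- best
  for (nm in unique(best)) {
    ks <- which(best == nm)
    if (length(ks) > 1) {
      ks <- ks[order(mass[ks], decreasing = TRUE)]
      out[ks] <- paste0(nm, "-", seq_along(ks))
    }
  }
  out
}
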