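# signed Newman modularity matrix terms for one weight matrix
.signed_B <- function(W) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  kp <- rowSums(Wp); kn <- rowSums(Wn)
  mp <- sum(kp); mn <- sum(kn)
  Bp <- if (mp > 0) Wp - outer(kp, kp) / mp else Wp * 0
  Bn <- if (mn > 0) Wn - outer(kn, kn) / mn else Wn * 0
  Bp - Bn
}

#' Optimal module count by spectral modularity
#'
#' Recursive Newman spectral bipartitioning of a signed weight matrix
#' (diagonal ignored): at each step the leading eigenvector of the
#' restricted signed modularity matrix splits the group in two, with a
#' Kernighan-Lin style single-swap refinement; splits are kept only
#' while the modularity gain is positive. The number of final
#' indivisible groups is the optimal module count.
#'
#' @param efc E x E symmetric (signed) connectivity matrix.
#' @return List with \code{k} (module count) and \code{labels}
#'   (length-E integer memberships).
#' @export
optimal_module_count <- function(efc) {
  W <- as.matrix(efc)
  diag(W) <- 0
  if (max(abs(W)) == 0 || sd(W[upper.tri(W)]) == 0)
    stop("constant connectivity matrix: no community structure")
  B <- .signed_B(W)
  n <- nrow(W)
  labels <- integer(n)
  next_id <- 1L

  split_group <- function(idx) {
    if (length(idx) < 2) {
      labels[idx] <<- next_id; next_id <<- next_id + 1L
      return(invisible())
    }
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)        # generalized modularity matrix
    ev <- eigen((Bg + t(Bg)) / 2, symmetric = TRUE)
    s <- ifelse(ev$vectors[, 1] >= 0, 1, -1)
    gain <- as.numeric(t(s) %*% Bg %*% s)
    # single-pass vertex-move refinement
    if (length(unique(s)) == 2) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (v in seq_along(idx)) {
          s2 <- s; s2[v] <- -s2[v]
          g2 <- as.numeric(t(s2) %*% Bg %*% s2)
          if (g2 > gain + 1e-12 && length(unique(s2)) == 2) {
            s <- s2; gain <- g2; improved <- TRUE
          }
        }
      }
    }
    if (gain > 1e-10 && length(unique(s)) == 2) {
      split_group(idx[s > 0])
      split_group(idx[s < 0])
    } else {
      labels[idx] <<- next_id; next_id <<- next_id + 1L
    }
    invisible()
  }
  split_group(seq_len(n))
  list(k = next_id - 1L, labels = labels)
}

#' Correlation-distance k-means over edges
#'
#' Groups the rows of the eFC matrix into k communities by k-means with
#' correlation distance (1 - Pearson between a row and its cluster's
#' mean row). Empty clusters are re-seeded at the point farthest from
#' its centroid; the best of \code{n_restarts} runs (lowest total
#' within-cluster distance) is returned.
#'
#' @param efc E x E connectivity matrix (rows are clustered).
#' @param k number of communities.
#' @param seed integer seed.
#' @param n_restarts random restarts (default 50).
#' @param max_iter iterations per restart.
#' @return List of class \code{edge_communities}: \code{labels}
#'   (length E), \code{k}, \code{within} (total within-cluster
#'   correlation distance).
#' @export
edge_kmeans <- function(efc, k, seed = 1L, n_restarts = 50L, max_iter = 100L) {
  X <- as.matrix(efc)
  E <- nrow(X)
  if (k > E) stop("k cannot exceed the number of edges")
  if (k == 1)
    return(structure(list(labels = rep(1L, E), k = 1L, within = 0),
                     class = "edge_communities"))

  cor_dist <- function(X, Cm) {
    # 1 - cor between each row of X and each centroid row
    Xs <- X - rowMeans(X)
    Cs <- Cm - rowMeans(Cm)
    nx <- sqrt(rowSums(Xs^2)); nx[nx == 0] <- .EPS
    nc <- sqrt(rowSums(Cs^2)); nc[nc == 0] <- .EPS
    1 - (Xs %*% t(Cs)) / outer(nx, nc)
  }

  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    cent <- X[sample.int(E, k), , drop = FALSE]
    lab <- integer(E)
    for (it in seq_len(max_iter)) {
      D <- cor_dist(X, cent)
      new_lab <- max.col(-D, ties.method = "first")
      # re-seed empty clusters at the farthest point of a multi-member
      # cluster (repeat until none empty; donors keep >= 1 member)
      repeat {
        empty <- setdiff(seq_len(k), unique(new_lab))
        if (length(empty) == 0) break
        own <- D[cbind(seq_len(E), new_lab)]
        elig <- which(tabulate(new_lab, k)[new_lab] > 1)
        far <- elig[which.max(own[elig])]
        new_lab[far] <- empty[1]
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
      for (c in seq_len(k))
        cent[c, ] <- colMeans(X[lab == c, , drop = FALSE])
    }
    D <- cor_dist(X, cent)
    within <- sum(D[cbind(seq_len(E), lab)])
    if (is.null(best) || within < best$within)
      best <- list(labels = lab, k = as.integer(k), within = within)
  }
  structure(best, class = "edge_communities")
}

#' Network membership counts per edge community
#'
#' Every edge connects two of the K networks; when the edge belongs to a
#' community, both endpoint networks count toward that community. Column
#' c therefore sums to twice the size of community c.
#'
#' @param labels length-E community labels.
#' @param pairs E x 2 edge index map (see \code{\link{edge_index}}).
#' @param K number of networks.
#' @return K x k count matrix.
#' @export
community_network_counts <- function(labels, pairs, K) {
  k <- max(labels)
  M <- matrix(0L, K, k)
  for (e in seq_along(labels)) {
    c <- labels[e]
    M[pairs[e, 1], c] <- M[pairs[e, 1], c] + 1L
    M[pairs[e, 2], c] <- M[pairs[e, 2], c] + 1L
  }
  M
}

#' Community-level functional connectivity
#'
#' Each community is represented by the mean of its member edge time
#' series; the output is the k x k Pearson correlation matrix between
#' the representatives. Constant representatives are zeroed with a
#' warning.
#'
#' @param ets an \code{\link{edge_time_series}} result or E x T matrix.
#' @param labels length-E community labels.
#' @return k x k symmetric correlation matrix with unit diagonal.
#' @export
community_fc <- function(ets, labels) {
  M <- if (inherits(ets, "edge_ts")) ets$ets else ets
  k <- max(labels)
  reps <- t(vapply(seq_len(k), function(c)
    colMeans(M[labels == c, , drop = FALSE]), numeric(ncol(M))))
  if (k == 1) return(matrix(1, 1, 1))
  v <- apply(reps, 1, var)
  C <- suppressWarnings(cor(t(reps)))
  if (any(v == 0)) {
    warning("constant community representative: correlations set to 0")
    C[v == 0, ] <- 0
    C[, v == 0] <- 0
  }
  diag(C) <- 1
  C
}
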