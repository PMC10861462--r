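# Brute-force graph-metric oracles, written directly from the binary
# definitions. Deliberately slow and independent of igraph.

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_nodal_cp <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(A[nb, nb]) / 2
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

bf_cp <- function(A) mean(bf_nodal_cp(A))

bf_lp <- function(A) {
  D <- bf_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d) & d > 0])
}

bf_eglob <- function(A) {
  if (nrow(A) < 2) return(0)
  D <- bf_distances(A)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_nodal_eloc <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    bf_eglob(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

bf_eloc <- function(A) mean(bf_nodal_eloc(A))

bf_assortativity <- function(A) {
  ed <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  deg <- rowSums(A)
  # both orientations of every edge
  x <- c(deg[ed[, 1]], deg[ed[, 2]])
  y <- c(deg[ed[, 2]], deg[ed[, 1]])
  suppressWarnings(cor(x, y))
}

# betweenness by exhaustive enumeration of all shortest paths (DFS)
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  bw <- numeric(n)
  all_paths <- function(i, j) {
    # enumerate all shortest i->j paths as lists of vertices
    res <- list()
    walk <- function(path, v) {
      if (v == j) { res[[length(res) + 1]] <<- path; return() }
      for (w in which(A[v, ] == 1))
        if (D[v, j] == D[w, j] + 1) walk(c(path, w), w)
    }
    walk(i, i)
    res
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.finite(D[i, j]) || D[i, j] == 0) next
    paths <- all_paths(i, j)
    if (length(paths) == 0) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner) > 0) {
      tab <- table(inner)
      bw[as.integer(names(tab))] <- bw[as.integer(names(tab))] +
        as.numeric(tab) / length(paths)
    }
  }
  bw
}

# all undirected simple graphs on n nodes, as adjacency matrices
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

# greedy one-to-one row matching score between two loading matrices
match_score <- function(est, truth) {
  M <- abs(suppressWarnings(cor(t(est), t(truth))))
  M[is.na(M)] <- 0
  K <- nrow(truth)
  out <- numeric(K)
  for (s in seq_len(K)) {
    ij <- which(M == max(M), arr.ind = TRUE)[1, ]
    out[s] <- M[ij[1], ij[2]]
    M[ij[1], ] <- -1
    M[, ij[2]] <- -1
  }
  mean(out)
}

# small test scan with known content
toy_scan <- function(V = 20, Tn = 40, tr = 2, seed = 1) {
  set.seed(seed)
  structure(list(signal = matrix(rnorm(V * Tn), V),
                 motion = matrix(rnorm(Tn * 6, sd = 0.01), Tn),
                 tr = tr, subject_id = "toy", group = "TD"),
            class = "subject_scan")
}
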