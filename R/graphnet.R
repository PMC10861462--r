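#' Threshold a correlation matrix by significance
#'
#' Keeps an edge when the two-sided p-value of its Pearson correlation
#' (t-transform with T - 2 degrees of freedom) is below \code{alpha},
#' and binarizes. By default significance is assessed on |r|, so
#' significant negative correlations are kept; set
#' \code{positive_only = TRUE} to keep positive edges only.
#'
#' @param C symmetric correlation matrix.
#' @param T_samples number of observations behind each correlation.
#' @param alpha significance level (default 0.05).
#' @param positive_only drop negative correlations.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
threshold_significant <- function(C, T_samples, alpha = 0.05,
                                  positive_only = FALSE) {
  if (T_samples < 4) stop("need at least 4 samples")
  df <- T_samples - 2
  r <- pmin(pmax(C, -1), 1)
  p <- matrix(0, nrow(C), ncol(C))
  sub <- abs(r) < 1
  tt <- abs(r[sub]) * sqrt(df / (1 - r[sub]^2))
  p[sub] <- 2 * pt(tt, df, lower.tail = FALSE)
  A <- (p < alpha) * 1
  if (positive_only) A[r <= 0] <- 0
  diag(A) <- 0
  A <- pmax(A, t(A))  # p is symmetric already; guard numerics
  A
}

.as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

# global efficiency: mean of 1/d over distinct pairs; disconnected -> 0
.eglob <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# local efficiency of one node: Eglob of its open neighbourhood subgraph
.eloc_node <- function(g, v) {
  nb <- igraph::neighbors(g, v)
  if (length(nb) < 2) return(0)
  .eglob(igraph::induced_subgraph(g, nb))
}

#' Global graph attributes
#'
#' Binary-graph definitions: Cp = mean nodal clustering (zero for
#' degree < 2 nodes), Lp = mean shortest path over connected pairs,
#' Eglob = mean inverse distance over distinct pairs (disconnected pairs
#' contribute 0), Eloc = mean over nodes of the global efficiency of
#' each node's neighbourhood subgraph, assortativity r = Pearson
#' correlation of end-node degrees over edges, and Q = Newman modularity
#' of the greedy-agglomerative partition.
#'
#' @param A binary symmetric adjacency matrix.
#' @return Named list: \code{Cp}, \code{Lp}, \code{Eglob}, \code{Eloc},
#'   \code{assortativity}, \code{Q}.
#' @export
global_metrics <- function(A) {
  g <- .as_igraph(A)
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) stop("empty graph")
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  Lp <- mean(du[is.finite(du) & du > 0])
  Eloc <- mean(vapply(seq_len(n), function(v) .eloc_node(g, v), numeric(1)))
  r <- suppressWarnings(igraph::assortativity_degree(g))
  comm <- igraph::cluster_fast_greedy(g)
  list(Cp = mean(cc), Lp = Lp, Eglob = .eglob(g), Eloc = Eloc,
       assortativity = r, Q = igraph::modularity(comm))
}

#' Nodal graph attributes
#'
#' Per node: degree (row sum), betweenness centrality (raw sum of
#' shortest-path pair fractions, plus the pair-normalized value),
#' nodal clustering coefficient and nodal local efficiency.
#'
#' @param A binary symmetric adjacency matrix.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{betweenness}, \code{betweenness_norm}, \code{Cp},
#'   \code{Eloc}.
#' @export
nodal_metrics <- function(A) {
  g <- .as_igraph(A)
  n <- igraph::vcount(g)
  bw <- igraph::betweenness(g, directed = FALSE)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  el <- vapply(seq_len(n), function(v) .eloc_node(g, v), numeric(1))
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  data.frame(node = seq_len(n), degree = as.numeric(rowSums(A)),
             betweenness = bw, betweenness_norm = bw / denom,
             Cp = cc, Eloc = el)
}

#' Degree-preserving random rewiring
#'
#' Double-edge-swap rewiring that preserves every node's degree exactly;
#' connectedness is not enforced. Used as the null model for the
#' small-world indices.
#'
#' @param A binary symmetric adjacency matrix.
#' @param n_swaps number of attempted swaps (default 10 x edge count).
#' @param seed integer seed.
#' @return Rewired adjacency matrix.
#' @export
degree_preserving_null <- function(A, n_swaps = NULL, seed = 1L) {
  g <- .as_igraph(A)
  m <- igraph::ecount(g)
  if (is.null(n_swaps)) n_swaps <- 10 * m
  set.seed(as.integer(seed))
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_swaps))
  as.matrix(igraph::as_adjacency_matrix(g2))
}

#' Small-world indices
#'
#' gamma = Cp / mean null Cp, lambda = Lp / mean null Lp and
#' sigma = gamma / lambda, with the null ensemble drawn by
#' degree-preserving rewiring. The returned criterion records the
#' conventional small-world check: gamma > 1, lambda within
#' \code{lambda_band}, sigma > 1.
#'
#' @param A binary symmetric adjacency matrix.
#' @param n_null number of null graphs (default 100).
#' @param seed integer seed.
#' @param lambda_band tolerance band for "lambda approximately 1".
#' @return List with \code{gamma}, \code{lambda}, \code{sigma},
#'   \code{criterion} (logical), and the null means.
#' @export
small_world <- function(A, n_null = 100L, seed = 1L,
                        lambda_band = c(0.8, 1.2)) {
  gm <- global_metrics(A)
  cp0 <- numeric(n_null); lp0 <- numeric(n_null)
  for (b in seq_len(n_null)) {
    An <- degree_preserving_null(A, seed = seed + b)
    g <- .as_igraph(An)
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    cc[is.na(cc)] <- 0
    cp0[b] <- mean(cc)
    d <- igraph::distances(g)
    du <- d[upper.tri(d)]
    lp0[b] <- mean(du[is.finite(du) & du > 0])
  }
  gamma <- gm$Cp / mean(cp0)
  lambda <- gm$Lp / mean(lp0)
  sigma <- gamma / lambda
  list(gamma = gamma, lambda = lambda, sigma = sigma,
       criterion = gamma > 1 && lambda >= lambda_band[1] &&
         lambda <= lambda_band[2] && sigma > 1,
       null_Cp = mean(cp0), null_Lp = mean(lp0))
}

#' All graph attributes of one thresholded connectivity matrix
#'
#' Convenience wrapper: significance-thresholds the correlation matrix
#' and returns the global metrics, small-world indices and nodal
#' metrics together.
#'
#' @param C correlation matrix.
#' @param T_samples observations behind each correlation.
#' @param alpha threshold significance level.
#' @param n_null small-world null count.
#' @param seed seed for nulls.
#' @return List with \code{adjacency}, \code{global}, \code{small_world}
#'   and \code{nodal}.
#' @export
graph_attributes <- function(C, T_samples, alpha = 0.05, n_null = 100L,
                             seed = 1L) {
  A <- threshold_significant(C, T_samples, alpha)
  list(adjacency = A,
       global = global_metrics(A),
       small_world = small_world(A, n_null = n_null, seed = seed),
       nodal = nodal_metrics(A))
}
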