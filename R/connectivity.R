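#' Node-wise functional network connectivity
#'
#' Pairwise Pearson correlations between the K network time courses.
#' Zero-variance columns get zero rows/columns with a warning (their
#' diagonal stays 1).
#'
#' @param tc T x K time-course matrix.
#' @return K x K symmetric correlation matrix with unit diagonal.
#' @export
node_fnc <- function(tc) {
  if (nrow(tc) < 3) stop("need at least 3 frames")
  v <- apply(tc, 2, var)
  C <- suppressWarnings(cor(tc))
  if (any(v == 0)) {
    warning("zero-variance time course(s): correlations set to 0")
    C[v == 0, ] <- 0
    C[, v == 0] <- 0
  }
  diag(C) <- 1
  C
}

#' Edge index map
#'
#' Lexicographic enumeration of the E = K(K-1)/2 ordered network pairs
#' (i < j), the row order used by all edge-level operations.
#'
#' @param K number of networks.
#' @return E x 2 integer matrix with columns \code{i}, \code{j}.
#' @export
edge_index <- function(K) {
  p <- which(upper.tri(diag(K)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("i", "j")
  p
}

#' Edge time series
#'
#' Z-scores each network time course with the population (1/T) variance
#' convention and forms, for every network pair i < j, the frame-wise
#' product \eqn{e_{ij}(t) = z_i(t) z_j(t)}. Under this scaling the time
#' average of each edge series equals the Pearson correlation of the
#' pair, so static FNC is exactly the mean of the co-fluctuation series.
#'
#' @param tc T x K time-course matrix.
#' @return List of class \code{edge_ts}: \code{ets} (E x T matrix) and
#'   \code{pairs} (\code{\link{edge_index}} map).
#' @export
edge_time_series <- function(tc) {
  Tn <- nrow(tc); K <- ncol(tc)
  if (Tn < 3) stop("need at least 3 frames")
  v <- apply(tc, 2, var) * (Tn - 1) / Tn
  if (any(v == 0)) stop("zero-variance time course")
  Z <- scale(tc, center = TRUE, scale = sqrt(v))
  p <- edge_index(K)
  ets <- t(Z[, p[, 1], drop = FALSE] * Z[, p[, 2], drop = FALSE])
  structure(list(ets = ets, pairs = p), class = "edge_ts")
}

#' Edge-wise functional connectivity (eFC)
#'
#' Pearson correlations between all pairs of edge time series; with
#' K = 17 networks this is the 136 x 136 edge-wise functional network.
#' Constant edge rows are zeroed with a warning.
#'
#' @param ets an \code{\link{edge_time_series}} result or an E x T
#'   matrix.
#' @return E x E symmetric correlation matrix with unit diagonal.
#' @export
edge_fnc <- function(ets) {
  M <- if (inherits(ets, "edge_ts")) ets$ets else ets
  v <- apply(M, 1, var)
  C <- suppressWarnings(cor(t(M)))
  if (any(v == 0)) {
    warning("constant edge time series: correlations set to 0")
    C[v == 0, ] <- 0
    C[, v == 0] <- 0
  }
  diag(C) <- 1
  C
}

#' RSS co-fluctuation amplitude profile
#'
#' The root-sum-square across edges at each frame is the global
#' co-fluctuation amplitude of that frame. Frames are ranked and the
#' top and bottom \code{frac} tails (k = ceiling(frac * T) frames each,
#' ties broken by earlier frame) are labelled T and B, the rest N.
#'
#' @param ets an \code{\link{edge_time_series}} result or E x T matrix.
#' @param frac tail fraction (0 < frac < 0.5), default 0.05.
#' @return List of class \code{rss_profile}: \code{rss} (length T),
#'   \code{top}, \code{bottom} (frame index sets) and \code{labels}
#'   (factor of B/N/T per frame).
#' @export
rss_profile <- function(ets, frac = 0.05) {
  if (frac <= 0 || frac >= 0.5) stop("frac must be in (0, 0.5)")
  M <- if (inherits(ets, "edge_ts")) ets$ets else ets
  rss <- sqrt(colSums(M^2))
  Tn <- length(rss)
  k <- ceiling(frac * Tn)
  ord_desc <- order(-rss, seq_len(Tn))
  ord_asc <- order(rss, seq_len(Tn))
  top <- sort(ord_desc[seq_len(k)])
  bottom <- sort(ord_asc[seq_len(k)])
  labels <- rep("N", Tn)
  labels[bottom] <- "B"
  labels[top] <- "T"
  structure(list(rss = rss, top = top, bottom = bottom,
                 labels = factor(labels, levels = c("B", "N", "T"))),
            class = "rss_profile")
}

#' Mean tail co-fluctuation amplitude
#'
#' Mean RSS over the top or bottom tail frames — the subject-level
#' summary compared across groups.
#'
#' @param profile an \code{\link{rss_profile}} result.
#' @param which \code{"top"} or \code{"bottom"}.
#' @return Scalar mean amplitude.
#' @export
tail_amplitude <- function(profile, which = c("top", "bottom")) {
  which <- match.arg(which)
  mean(profile$rss[profile[[which]]])
}

#' Count amplitude-level transitions
#'
#' Counts the T-1 consecutive-frame transitions between the bottom (B),
#' normal (N) and top (T) amplitude levels, including self-transitions.
#'
#' @param labels vector/factor of per-frame levels in \{B, N, T\}.
#' @return 3 x 3 integer matrix, rows = from, cols = to, in B, N, T
#'   order; entries sum to T - 1.
#' @export
count_transitions <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("empty label sequence")
  stopifnot(all(labels %in% c("B", "N", "T")))
  lv <- c("B", "N", "T")
  M <- matrix(0L, 3, 3, dimnames = list(from = lv, to = lv))
  if (length(labels) > 1) {
    from <- factor(labels[-length(labels)], levels = lv)
    to <- factor(labels[-1], levels = lv)
    M[] <- table(from, to)
  }
  M
}
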