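#' ANCOVA group test with one covariate
#'
#' Partial (type-II) F-test of the group factor in the linear model
#' \code{y ~ group + covariate}: the reduced model keeps the covariate,
#' the full model adds the group indicators, and
#' F = ((RSS_reduced - RSS_full)/(g-1)) / (RSS_full/(n-g-1)).
#' If the covariate is collinear with the group indicators the test
#' falls back to a one-way ANOVA with a warning.
#'
#' @param y numeric response of length n.
#' @param group factor (or coercible) of length n, >= 2 levels with
#'   >= 2 observations each.
#' @param covariate numeric covariate of length n.
#' @return List with \code{F}, \code{p}, \code{df} (numerator,
#'   denominator) and \code{covariate_coef}.
#' @export
ancova <- function(y, group, covariate) {
  group <- droplevels(as.factor(group))
  g <- nlevels(group)
  n <- length(y)
  stopifnot(g >= 2, all(table(group) >= 2), length(covariate) == n)
  if (var(y) == 0)
    return(list(F = 0, p = 1, df = c(g - 1, n - g - 1),
                covariate_coef = 0))
  Xg <- model.matrix(~group)
  Xf <- cbind(Xg, covariate)
  if (qr(Xf)$rank < ncol(Xf)) {
    warning("covariate collinear with group: falling back to one-way ANOVA")
    return(c(anova_oneway(y, group), covariate_coef = NA_real_))
  }
  fit_full <- lm.fit(Xf, y)
  fit_red <- lm.fit(cbind(1, covariate), y)
  rss_f <- sum(fit_full$residuals^2)
  rss_r <- sum(fit_red$residuals^2)
  df1 <- g - 1
  df2 <- n - g - 1
  Fv <- if (rss_f == 0) 0 else ((rss_r - rss_f) / df1) / (rss_f / df2)
  Fv <- max(Fv, 0)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), df = c(df1, df2),
       covariate_coef = unname(fit_full$coefficients["covariate"]))
}

#' One-way ANOVA
#'
#' Classic between/within F-test across groups.
#'
#' @param y numeric response.
#' @param group factor of group labels.
#' @return List with \code{F}, \code{p} and \code{df}.
#' @export
anova_oneway <- function(y, group) {
  group <- droplevels(as.factor(group))
  if (var(y) == 0)
    return(list(F = 0, p = 1, df = c(nlevels(group) - 1,
                                     length(y) - nlevels(group))))
  fit <- aov(y ~ group)
  tab <- anova(fit)
  Fv <- tab$`F value`[1]
  if (is.na(Fv)) Fv <- 0
  p <- tab$`Pr(>F)`[1]
  if (is.na(p)) p <- 1
  list(F = Fv, p = p, df = tab$Df)
}

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected (classic) Pearson statistic on the observed counts.
#'
#' @param tab contingency table (matrix of counts).
#' @return List with \code{X2}, \code{p} and \code{df}.
#' @export
chi_square <- function(tab) {
  res <- suppressWarnings(chisq.test(as.matrix(tab), correct = FALSE))
  list(X2 = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Pairwise post-hoc two-sample t-tests
#'
#' Two-sided equal-variance (pooled) t-tests for the requested group
#' pairs, with df = n1 + n2 - 2.
#'
#' @param y numeric response.
#' @param group factor of group labels.
#' @param pairs list of length-2 character vectors of group labels; by
#'   default every pair of levels.
#' @param var_equal pooled-variance test (classic post-hoc) when TRUE,
#'   Welch otherwise.
#' @return data.frame with columns \code{group1}, \code{group2},
#'   \code{t}, \code{p}.
#' @export
posthoc_ttests <- function(y, group, pairs = NULL, var_equal = TRUE) {
  group <- droplevels(as.factor(group))
  if (is.null(pairs)) {
    lv <- levels(group)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  res <- lapply(pairs, function(pr) {
    y1 <- y[group == pr[1]]; y2 <- y[group == pr[2]]
    tt <- stats::t.test(y1, y2, var.equal = var_equal)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg FDR
#'
#' Step-up false-discovery-rate control: returns the BH-adjusted
#' p-values and the rejection mask at level \code{q}.
#'
#' @param pvals numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return List with \code{rejected} (logical) and \code{adjusted}
#'   (numeric).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  adj <- p.adjust(pvals, method = "BH")
  list(rejected = adj <= q, adjusted = adj)
}

#' ANCOVA-gated feature screen with pooled FDR
#'
#' For every feature column: an ANCOVA of feature ~ group + covariate
#' gates at \code{alpha}; gated features get all pairwise post-hoc
#' t-tests, and BH-FDR at \code{q} is applied across the pooled family
#' of all gated pair-by-feature tests.
#'
#' @param features n x m matrix (named columns) of subject-level
#'   features.
#' @param group factor of length n.
#' @param covariate numeric covariate of length n (e.g. mean FD).
#' @param alpha ANCOVA gate level (default 0.05).
#' @param q FDR level for the post-hoc family (default 0.05).
#' @param var_equal pooled-variance post-hoc tests when TRUE.
#' @return List with \code{omnibus} (data.frame: feature, F, p, gated)
#'   and \code{posthoc} (data.frame: feature, group1, group2, t, p,
#'   p_fdr, significant), the latter with one row per gated
#'   pair-by-feature test.
#' @export
feature_screen <- function(features, group, covariate, alpha = 0.05,
                           q = 0.05, var_equal = TRUE) {
  features <- as.matrix(features)
  m <- ncol(features)
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("f", seq_len(m))
  if (m == 0)
    return(list(omnibus = data.frame(feature = character(0), F = numeric(0),
                                     p = numeric(0), gated = logical(0)),
                posthoc = data.frame()))
  om <- lapply(seq_len(m), function(j) {
    a <- ancova(features[, j], group, covariate)
    data.frame(feature = fn[j], F = a$F, p = a$p, gated = a$p < alpha,
               stringsAsFactors = FALSE)
  })
  omnibus <- do.call(rbind, om)
  ph <- lapply(which(omnibus$gated), function(j) {
    d <- posthoc_ttests(features[, j], group, var_equal = var_equal)
    d$feature <- fn[j]
    d[, c("feature", "group1", "group2", "t", "p")]
  })
  posthoc <- if (length(ph) > 0) do.call(rbind, ph) else
    data.frame(feature = character(0), group1 = character(0),
               group2 = character(0), t = numeric(0), p = numeric(0))
  if (nrow(posthoc) > 0) {
    fd <- fdr_bh(posthoc$p, q)
    posthoc$p_fdr <- fd$adjusted
    posthoc$significant <- fd$rejected
  } else {
    posthoc$p_fdr <- numeric(0)
    posthoc$significant <- logical(0)
  }
  rownames(posthoc) <- NULL
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Correlations between neural indices and clinical scores
#'
#' Pairwise Pearson correlations between every metric column and every
#' score column, with t-based two-sided p-values and BH-FDR across all
#' m x s tests.
#'
#' @param metrics n x m matrix of neural indices.
#' @param scores n x s matrix of clinical scores.
#' @param q FDR level (default 0.05).
#' @return List with \code{r}, \code{p} (m x s matrices) and
#'   \code{significant} (logical m x s mask after FDR).
#' @export
clinical_correlations <- function(metrics, scores, q = 0.05) {
  metrics <- as.matrix(metrics); scores <- as.matrix(scores)
  n <- nrow(metrics)
  stopifnot(nrow(scores) == n, n >= 4)
  r <- cor(metrics, scores)
  df <- n - 2
  tt <- abs(r) * sqrt(df / pmax(1 - r^2, .EPS))
  p <- 2 * pt(tt, df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  fd <- fdr_bh(as.vector(p), q)
  sig <- matrix(fd$rejected, nrow(p), ncol(p), dimnames = dimnames(p))
  list(r = r, p = p, significant = sig)
}
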