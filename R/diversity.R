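#' Per-sample alpha diversity indices
#'
#' Shannon uses the natural log; evenness is Pielou's `H / ln(S)` (0 when
#' a single species is observed); Simpson is the Gini-Simpson form
#' `1 - sum p^2`; Chao1 is bias-corrected, `S + F1 (F1 - 1) / (2 (F2 + 1))`,
#' and ACE uses the standard rare/abundant split at 10 reads (both via
#' [vegan::estimateR()]).
#'
#' @param t a [count_table()] or taxa x samples count matrix.
#' @return data.frame per sample: `observed`, `shannon`, `simpson`,
#'   `evenness`, `chao1`, `ace`.
#' @export
alpha_diversity <- function(t) {
  m <- if (inherits(t, "count_table")) t$counts else as.matrix(t)
  if (any(colSums(m) <= 0)) stopf("all sample totals must be positive")
  x <- t(m)
  sh <- vegan::diversity(x, index = "shannon")
  si <- vegan::diversity(x, index = "simpson")
  obs <- rowSums(x > 0)
  ev <- ifelse(obs > 1, sh / log(obs), 0)
  ## estimateR can produce NaN *standard errors* (e.g. no singletons);
  ## only the point estimates are consumed here
  est <- suppressWarnings(vegan::estimateR(round(x)))
  data.frame(sample = rownames(x), observed = obs, shannon = sh,
             simpson = si, evenness = ev,
             chao1 = est["S.chao1", ], ace = est["S.ACE", ],
             row.names = rownames(x), stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; a semi-metric in
#' `[0, 1]` for non-negative data. A pair of all-zero samples is defined
#' to have distance 0 (with a warning).
#'
#' @param m taxa x samples matrix (counts or proportions) or a
#'   [count_table()].
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(m) {
  x <- if (inherits(m, "count_table")) m$counts else as.matrix(m)
  if (any(x < 0)) stopf("Bray-Curtis requires non-negative data")
  d <- vegan::vegdist(t(x), method = "bray")
  if (anyNA(d)) {
    warnf("all-zero sample pair(s); their Bray-Curtis distance is set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition of a distance matrix.
#' Axes are ordered by decreasing eigenvalue; negative eigenvalues are
#' reported but excluded from the proportion-explained denominator.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k maximum number of axes to return (default all positive).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, sorted), `proportion` (per returned axis).
#' @export
pcoa <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  ## cmdscale warns when fewer than k eigenvalues are positive; expected
  res <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- res$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(k %||% pos, pos)
  coords <- res$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion = eig[seq_len(k)] / sum(pmax(eig, 0))),
            class = "pcoa_result")
}

#' Distance-based PERMANOVA
#'
#' Pseudo-F partition of a distance matrix by group labels with a seeded
#' free permutation test (via [vegan::adonis2()]); the p-value is
#' `(1 + #permuted F >= observed) / (1 + n_perm)`.
#'
#' @param d `dist` object.
#' @param groups group labels, one per sample; every group needs >= 2
#'   samples and >= 2 groups are required.
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory: permutations are always seeded).
#' @return list: `f` (pseudo-F), `p`, `r2`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed) {
  if (missing(seed)) stopf("permanova requires an explicit seed")
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stopf("groups length != number of samples")
  tb <- table(groups)
  if (length(tb) < 2) stopf("need at least 2 groups")
  if (any(tb < 2))
    stopf("group(s) of size 1: %s", paste(names(tb)[tb < 2], collapse = ", "))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                        permutations = n_perm)
  list(f = fit$F[1], p = fit$`Pr(>F)`[1], r2 = fit$R2[1], n_perm = n_perm)
}
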