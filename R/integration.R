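#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimization by iterative majorization with monotone
#' regression (via [vegan::metaMDS()] on a precomputed distance matrix),
#' best of `n_restarts` seeded random starts.
#'
#' @param d `dist` object.
#' @param k target dimension.
#' @param seed integer seed (mandatory).
#' @param n_restarts random restarts.
#' @return list of class `nmds_result`: `points` (samples x k), `stress`
#'   (fraction, 0-1), `converged`.
#' @export
nmds_ordination <- function(d, k = 2, seed, n_restarts = 10) {
  if (missing(seed)) stopf("nmds requires an explicit seed")
  d <- stats::as.dist(d)
  if (attr(d, "Size") < k + 2) stopf("need at least k + 2 samples")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  if (!fit$converged)
    warnf("NMDS did not converge in %d restarts; best configuration returned",
          n_restarts)
  structure(list(points = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged)),
            class = "nmds_result")
}

#' Procrustes concordance with PROTEST significance
#'
#' Symmetric Procrustes: both configurations are centered and scaled to
#' unit total variance, the optimal rotation comes from the singular
#' decomposition of the cross-product, and the statistic is the residual
#' `M^2 = 1 - (sum of singular values)^2`, in `[0, 1]`. Significance is
#' the PROTEST permutation test: `p = (1 + #permuted M^2 <= observed) /
#' (1 + n_perm)` under row permutations of `Y` (via [vegan::protest()]).
#'
#' @param X,Y matched configurations (same row labels).
#' @param n_perm number of permutations (reference default 10000).
#' @param seed integer seed (mandatory).
#' @return list of class `procrustes_result`: `m2`, `p`, `correlation`
#'   (`sqrt(1 - M^2)`), `n_perm`.
#' @export
procrustes_protest <- function(X, Y, n_perm = 10000, seed) {
  if (missing(seed)) stopf("PROTEST requires an explicit seed")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have the same rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stopf("row labels of X and Y do not match")
  set.seed(seed)
  pr <- vegan::protest(X, Y, permutations = n_perm, symmetric = TRUE)
  structure(list(m2 = pr$ss, p = pr$signif, correlation = pr$t0,
                 n_perm = n_perm),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes M^2 = %.4f, PROTEST p = %.4g (%d permutations)\n",
              x$m2, x$p, x$n_perm))
  invisible(x)
}

#' Distance-based redundancy analysis
#'
#' Principal coordinates of the distance matrix regressed on the
#' constraint variables (via [vegan::dbrda()]); the constrained
#' proportion is the constrained inertia over the total
#' positive-eigenvalue inertia. Constant and aliased (collinear)
#' constraint columns are dropped with a warning.
#'
#' @param d `dist` object.
#' @param constraints data.frame of explanatory variables (rows =
#'   samples, in distance order).
#' @return list of class `dbrda_result`: `constrained_prop`,
#'   `eigenvalues` (constrained axes), `dropped` (columns removed),
#'   `model` (the vegan fit).
#' @export
db_rda <- function(d, constraints) {
  d <- stats::as.dist(d)
  constraints <- as.data.frame(constraints)
  if (nrow(constraints) != attr(d, "Size"))
    stopf("constraint rows must match samples")
  const <- vapply(constraints, function(x) length(unique(x)) < 2, logical(1))
  dropped <- names(constraints)[const]
  if (length(dropped) > 0) {
    warnf("constant constraint column(s) dropped: %s",
          paste(dropped, collapse = ", "))
    constraints <- constraints[, !const, drop = FALSE]
  }
  if (ncol(constraints) == 0) stopf("no usable constraint columns")
  fit <- vegan::dbrda(d ~ ., data = constraints)
  alias <- tryCatch(stats::alias(fit, names = TRUE),
                    error = function(e) character(0))
  if (length(alias) > 0) {
    warnf("rank-deficient constraints; aliased term(s): %s",
          paste(alias, collapse = ", "))
    dropped <- c(dropped, alias)
  }
  ## proportion over the positive-eigenvalue inertia (negative, imaginary
  ## axes of the semi-metric distance are excluded from the denominator)
  pos <- function(e) sum(e[e > 0])
  structure(list(constrained_prop = pos(fit$CCA$eig) /
                   (pos(fit$CCA$eig) + pos(fit$CA$eig)),
                 eigenvalues = fit$CCA$eig, dropped = dropped, model = fit),
            class = "dbrda_result")
}

#' Pairwise Spearman correlation grid between two feature blocks
#'
#' Tie-corrected Spearman r and p for every feature pair, with
#' Benjamini-Hochberg adjustment across the full grid. Constant features
#' yield `NA` entries (flagged undefined).
#'
#' @param A,B subject x feature matrices/data.frames sharing subjects
#'   (by rowname; >= 5 common subjects required).
#' @return list of class `correlation_grid`: `r`, `p`, `q` matrices
#'   (features of A x features of B).
#' @export
correlation_grid <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  common <- intersect(rownames(A) %||% character(0),
                      rownames(B) %||% character(0))
  if (length(common) >= 5) {
    A <- A[common, , drop = FALSE]; B <- B[common, , drop = FALSE]
  } else if (nrow(A) != nrow(B) || nrow(A) < 5) {
    stopf("subject overlap < 5")
  }
  r <- p <- matrix(NA_real_, ncol(A), ncol(B),
                   dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A))) {
    xi <- A[, i]
    if (length(unique(xi)) < 2) next
    for (j in seq_len(ncol(B))) {
      yj <- B[, j]
      if (length(unique(yj)) < 2) next
      ct <- suppressWarnings(stats::cor.test(xi, yj, method = "spearman",
                                             exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  q <- matrix(bh_adjust(as.vector(p)), nrow(r), ncol(r),
              dimnames = dimnames(r))
  structure(list(r = r, p = p, q = q), class = "correlation_grid")
}

#' Multivariable ordinary least squares with Wald intervals
#'
#' Least squares via QR ([stats::lm()]); per-coefficient two-sided p and
#' 95% confidence intervals from t quantiles with `n - p - 1` degrees of
#' freedom. A singular design is rejected naming the offending columns.
#'
#' @param y numeric outcome.
#' @param X data.frame of predictors (factors allowed; treatment coding
#'   with the first level as reference).
#' @param conf_level confidence level.
#' @return list of class `regression_fit`: `coefficients` (data.frame:
#'   term, beta, se, ci_lo, ci_hi, p), `n`, `r_squared`.
#' @export
multivariable_ols <- function(y, X, conf_level = 0.95) {
  X <- as.data.frame(X)
  if (length(y) != nrow(X)) stopf("length(y) != nrow(X)")
  if (length(y) <= ncol(X) + 1) stopf("need n > p + 1 observations")
  fit <- stats::lm(y ~ ., data = X)
  if (any(is.na(stats::coef(fit))))
    stopf("singular design; offending column(s): %s",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  co <- data.frame(term = rownames(sm$coefficients),
                   beta = sm$coefficients[, 1],
                   se = sm$coefficients[, 2],
                   ci_lo = ci[, 1], ci_hi = ci[, 2],
                   p = sm$coefficients[, 4],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = co, n = length(y),
                 r_squared = sm$r.squared, model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Gene-score association summary
#'
#' Spearman correlation of the pathway burden (`gene_score`) with CARS
#' and, when supplied, with alpha-diversity indices — a named wrapper
#' over [correlation_grid()].
#'
#' @param clinical clinical table containing a `gene_score` column
#'   (rownames = subjects).
#' @param alpha_table optional [alpha_diversity()] result to correlate
#'   against (shannon/simpson/evenness...).
#' @return data.frame: `against`, `r`, `p`.
#' @export
gene_score_association <- function(clinical, alpha_table = NULL) {
  if (is.null(clinical$gene_score)) stopf("clinical lacks a gene_score column")
  A <- matrix(clinical$gene_score, dimnames = list(rownames(clinical),
                                                   "gene_score"))
  B <- matrix(clinical$cars, dimnames = list(rownames(clinical), "cars"))
  if (!is.null(alpha_table)) {
    at <- as.matrix(alpha_table[, c("shannon", "simpson", "evenness")])
    rownames(at) <- rownames(alpha_table)
    common <- intersect(rownames(B), rownames(at))
    B <- cbind(B[common, , drop = FALSE], at[common, , drop = FALSE])
    A <- A[common, , drop = FALSE]
  }
  g <- correlation_grid(A, B)
  data.frame(against = colnames(g$r), r = g$r[1, ], p = g$p[1, ],
             row.names = NULL, stringsAsFactors = FALSE)
}
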