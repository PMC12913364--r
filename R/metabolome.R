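## fixed module color palette, assigned by decreasing module size
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Preprocess an intensity matrix for module detection
#'
#' Log-transforms (`log(1 + x)`) and retains the `top_k` most variable
#' metabolites (ties kept in input order). `top_k` larger than the
#' number of metabolites is clamped with a warning.
#'
#' @param m samples x metabolites non-negative intensity matrix.
#' @param top_k number of metabolites to keep by variance.
#' @return The log-scale samples x top_k matrix; the selected names are
#'   in `attr(, "selected")`.
#' @export
preprocess_intensities <- function(m, top_k = 1000) {
  m <- as.matrix(m)
  if (top_k > ncol(m)) {
    warnf("top_k (%d) exceeds metabolite count (%d); clamped", top_k, ncol(m))
    top_k <- ncol(m)
  }
  lx <- log1p(m)
  v <- apply(lx, 2, stats::var)
  sel <- order(v, decreasing = TRUE)[seq_len(top_k)]
  sel <- sort(sel)                  # preserve input order among selected
  out <- lx[, sel, drop = FALSE]
  attr(out, "selected") <- colnames(m)[sel]
  out
}

#' Volcano-style differential metabolite screening
#'
#' Per-metabolite two-sided Mann-Whitney p, BH q, and case-vs-control
#' log2 fold change of the raw-scale group means (pseudo-count 1). A
#' metabolite is called `up`/`down` when `q < alpha` and
#' `|log2FC| >= fc_min`.
#'
#' @param m samples x metabolites raw intensity matrix.
#' @param groups two-level labels, one per sample (each level >= 3).
#' @param case the case level (default `"ASD"` when present, else the
#'   first level).
#' @param fc_min minimum |log2 fold change|.
#' @param alpha q-value threshold.
#' @return data.frame per metabolite: `log2fc`, `p`, `q`, `call`.
#' @export
volcano <- function(m, groups, case = NULL, fc_min = 1, alpha = 0.05) {
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("volcano requires exactly two groups")
  if (any(table(groups) < 3)) stopf("each group needs >= 3 samples")
  case <- case %||% (if ("ASD" %in% levels(groups)) "ASD" else levels(groups)[1])
  if (!case %in% levels(groups)) stopf("unknown case level '%s'", case)
  ic <- groups == case
  p <- apply(m, 2, function(x) {
    if (length(unique(x)) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(x[ic], x[!ic])$p.value)
  })
  l2fc <- log2((colMeans(m[ic, , drop = FALSE]) + 1) /
                 (colMeans(m[!ic, , drop = FALSE]) + 1))
  q <- bh_adjust(p)
  call <- ifelse(q < alpha & l2fc >= fc_min, "up",
                 ifelse(q < alpha & l2fc <= -fc_min, "down", "ns"))
  data.frame(metabolite = colnames(m), log2fc = l2fc, p = p, q = q,
             call = call, row.names = colnames(m), stringsAsFactors = FALSE)
}

#' PLS-DA variable importance in projection
#'
#' Partial-least-squares discriminant fit of the standardized intensity
#' matrix against the class indicator (via [mixOmics::plsda()]), with
#' VIP by the standard weighted-loadings formula, so that
#' `mean(VIP^2) = 1`. Zero-variance metabolites are dropped with a
#' warning and reported with VIP `NA`.
#'
#' @param m samples x metabolites matrix.
#' @param groups two-level labels.
#' @param n_components number of PLS components.
#' @return Named numeric vector of VIPs (cumulative over components).
#' @export
pls_da_vip <- function(m, groups, n_components = 2) {
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("PLS-DA requires exactly two groups")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) warnf("%d zero-variance metabolite(s) dropped", sum(v == 0))
  keep <- v > 0
  fit <- mixOmics::plsda(m[, keep, drop = FALSE], groups,
                         ncomp = min(n_components, sum(keep) - 1))
  vip <- mixOmics::vip(fit)
  out <- rep(NA_real_, ncol(m))
  names(out) <- colnames(m)
  out[colnames(m)[keep]] <- vip[, ncol(vip)]
  out
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, the unsigned adjacency is
#' `|cor(i, j)|^beta` (Pearson, on the preprocessed log scale) and the
#' connectivity `k_i = sum_{j != i} a_ij`. Connectivities are binned
#' (10 bins), and the linear fit of `log10(frequency)` on
#' `log10(mean k)` gives the signed scale-free fit
#' `R^2 = -sign(slope) * r^2`. The chosen power is the smallest with
#' `R^2 >= r2_min`; if none reaches the threshold, the argmax is
#' returned with `reached = FALSE`.
#'
#' @param m preprocessed samples x metabolites matrix (>= 20 metabolites).
#' @param powers candidate integer powers.
#' @param r2_min scale-free fit threshold.
#' @param n_bins histogram bins for the fit.
#' @param min_mean_k smallest mean connectivity at which the fit is
#'   assessable; powers shrinking the network below this are never
#'   eligible (a near-empty adjacency is trivially "scale-free").
#' @return list of class `scale_free_fit`: `table` (power, r2, mean_k),
#'   `power`, `reached`.
#' @export
pick_soft_threshold <- function(m, powers = 1:20, r2_min = 0.85, n_bins = 10,
                                min_mean_k = 5) {
  m <- as.matrix(m)
  if (ncol(m) < 20) stopf("need >= 20 metabolites")
  if (any(apply(m, 2, stats::var) == 0))
    stopf("constant metabolite columns must be removed before fitting")
  ac <- abs(stats::cor(m))
  diag(ac) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    A <- ac^b
    k <- colSums(A)
    ## a collapsed network cannot be assessed for scale-freeness
    r2 <- if (mean(k) < min_mean_k) NA_real_ else scale_free_r2(k, n_bins)
    data.frame(power = b, r2 = r2, mean_k = mean(k))
  }))
  ok <- which(!is.na(tab$r2) & tab$r2 >= r2_min)
  reached <- length(ok) > 0
  if (all(is.na(tab$r2))) stopf("no power had assessable connectivity")
  power <- if (reached) tab$power[ok[1]] else
    tab$power[which.max(replace(tab$r2, is.na(tab$r2), -Inf))]
  if (!reached)
    warnf("no power reached scale-free R^2 >= %.2f; using argmax (power %d)",
          r2_min, power)
  structure(list(table = tab, power = power, reached = reached),
            class = "scale_free_fit")
}

## signed scale-free topology fit index of a connectivity vector
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- log10(kmean[keep]); y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Unsigned soft-thresholded adjacency
#'
#' @param m samples x metabolites matrix.
#' @param beta soft-thresholding power (>= 1).
#' @return metabolites x metabolites adjacency, diagonal 0.
#' @export
adjacency_matrix <- function(m, beta) {
  if (beta < 1) stopf("beta must be >= 1")
  A <- abs(stats::cor(as.matrix(m)))^beta
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; symmetric with entries in `[0, 1]`. Note that
#' `TOM_ij >= a_ij` does not hold in general.
#'
#' @param A symmetric adjacency with zero diagonal and entries in
#'   `[0, 1]`.
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(A) {
  A <- as.matrix(A)
  stopifnot(isSymmetric(unname(A)))
  if (any(A < 0 | A > 1)) stopf("adjacency entries must lie in [0, 1]")
  diag(A) <- 0
  k <- colSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by tree cut
#'
#' Average-linkage hierarchical clustering on `1 - TOM` with a
#' gap-guided static cut and recursive sub-branch inspection. The cut
#' falls at the midpoint of the widest gap between consecutive sorted
#' merge heights in the upper half of the dendrogram (tight
#' within-module merges sit low, background merges accumulate near 1,
#' and the widest gap separates the two regimes). Clusters of at least
#' `min_size` members become modules; the remaining pool is re-clustered
#' recursively so that compact branches completing above the first cut
#' are still found. A cluster of at least `min_size` members is accepted
#' as a module only if it is cohesive: its mean within-cluster
#' dissimilarity must be below `cohesion` times its mean dissimilarity
#' to the rest of the pool it was cut from (an unstructured pool
#' produces clusters no tighter than their surroundings, which stops
#' the recursion). Leftover
#' metabolites are `"grey"`; modules are labelled by decreasing size
#' from the fixed palette (turquoise, blue, brown, ...). An explicit
#' `cut_height` disables the gap rule, the recursion and the cohesion
#' test.
#'
#' @param tom TOM similarity matrix (named).
#' @param min_size minimum module size.
#' @param cut_height optional fixed dissimilarity at which to cut once.
#' @param cohesion largest acceptable ratio of mean within-cluster to
#'   mean cluster-to-rest dissimilarity.
#' @return Named character vector metabolite -> color (class
#'   `module_partition`); module sizes in `attr(, "sizes")`.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = NULL,
                           cohesion = 0.9) {
  tom <- as.matrix(tom)
  ids <- colnames(tom) %||% as.character(seq_len(ncol(tom)))
  colnames(tom) <- rownames(tom) <- ids
  color <- stats::setNames(rep("grey", ncol(tom)), ids)

  within_dissim <- function(members) {
    d <- 1 - tom[members, members]
    mean(d[upper.tri(d)])
  }
  clusters <- list()
  pool <- ids
  repeat {
    if (length(pool) < min_size) break
    h <- stats::hclust(stats::as.dist(1 - tom[pool, pool]), method = "average")
    gc <- gap_cut_height(h$height)
    cl <- stats::cutree(h, h = cut_height %||% gc$height)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_size]
    taken <- character(0)
    for (b in big) {
      members <- pool[cl == as.integer(b)]
      rest <- setdiff(pool, members)
      between <- if (length(rest) > 0) mean(1 - tom[members, rest]) else NA
      cohesive <- is.finite(between) &&
        within_dissim(members) < cohesion * between
      if (!is.null(cut_height) || cohesive) {
        clusters <- c(clusters, list(members))
        taken <- c(taken, members)
      }
    }
    pool <- setdiff(pool, taken)
    if (length(taken) == 0 || !is.null(cut_height)) break
  }
  if (length(clusters) > 0) {
    ord <- order(-lengths(clusters))
    for (i in seq_along(ord)) {
      lab <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else
        sprintf("module%02d", i)
      color[clusters[[ord[i]]]] <- lab
    }
  }
  out <- color
  class(out) <- c("module_partition", class(out))
  attr(out, "sizes") <- sort(table(color[color != "grey"]), decreasing = TRUE)
  out
}

## midpoint and width of the widest gap between consecutive sorted merge
## heights, restricted to heights above the midrange (gaps among the
## earliest, within-module merges are not cut candidates)
gap_cut_height <- function(heights) {
  hs <- sort(unique(heights))
  if (length(hs) < 2) return(list(height = max(hs) / 2, gap = max(hs)))
  lo <- min(hs) + diff(range(hs)) / 2
  i <- which(hs[-length(hs)] >= lo | hs[-1] >= lo)
  gaps <- hs[i + 1] - hs[i]
  j <- i[which.max(gaps)]
  list(height = (hs[j] + hs[j + 1]) / 2, gap = max(gaps))
}

#' Module eigenprofiles
#'
#' First principal component of each non-grey module's standardized
#' member columns (unit-norm sample-length profile), oriented so that
#' its mean correlation with the members is non-negative, with the
#' variance explained by the component.
#'
#' @param m samples x metabolites matrix (same scale used for module
#'   detection).
#' @param partition a [detect_modules()] result.
#' @return list of class `module_eigenprofiles`: `profiles` (samples x
#'   modules matrix), `var_explained` (named numeric).
#' @export
eigenprofiles <- function(m, partition) {
  m <- as.matrix(m)
  mods <- setdiff(unique(partition), "grey")
  if (length(mods) == 0) stopf("no non-grey modules")
  ## order by size (palette order)
  mods <- mods[order(match(mods, MODULE_COLORS))]
  prof <- matrix(NA_real_, nrow(m), length(mods),
                 dimnames = list(rownames(m), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (md in mods) {
    sub <- scale(m[, names(partition)[partition == md], drop = FALSE])
    sv <- svd(sub, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (mean(stats::cor(e, sub)) < 0) e <- -e
    prof[, md] <- e
    ve[md] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(profiles = prof, var_explained = ve),
            class = "module_eigenprofiles")
}

#' Module-trait Spearman correlation matrix
#'
#' @param eigen a [eigenprofiles()] result (or samples x modules matrix).
#' @param clinical clinical table with rownames = sample ids.
#' @param traits clinical columns to correlate (binary traits are
#'   rank-encoded automatically; constant traits are flagged `NA`).
#' @return list of class `module_trait_matrix`: `r` and `p` matrices
#'   (modules x traits).
#' @export
module_trait <- function(eigen, clinical,
                         traits = c("diarrhea", "constipation", "insomnia",
                                    "cars", "abc")) {
  prof <- if (inherits(eigen, "module_eigenprofiles")) eigen$profiles else
    as.matrix(eigen)
  common <- intersect(rownames(prof), rownames(clinical))
  if (length(common) < 5) stopf("sample overlap < 5")
  prof <- prof[common, , drop = FALSE]
  cl <- clinical[common, , drop = FALSE]
  r <- p <- matrix(NA_real_, ncol(prof), length(traits),
                   dimnames = list(colnames(prof), traits))
  for (tr in traits) {
    y <- as.numeric(cl[[tr]])
    if (length(unique(y)) < 2) next   # constant trait stays NA-flagged
    for (md in colnames(prof)) {
      ct <- suppressWarnings(stats::cor.test(prof[, md], y,
                                             method = "spearman", exact = FALSE))
      r[md, tr] <- unname(ct$estimate)
      p[md, tr] <- ct$p.value
    }
  }
  structure(list(r = r, p = p), class = "module_trait_matrix")
}
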