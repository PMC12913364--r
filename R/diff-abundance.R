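#' Per-taxon differential abundance screening
#'
#' Mann-Whitney for two groups, Kruskal-Wallis for three or more, with
#' Benjamini-Hochberg adjustment across taxa. Constant (including
#' all-zero) taxa get p = 1 by convention. Direction is the group with
#' the highest mean abundance.
#'
#' @param rel taxa x samples matrix of proportions (or counts).
#' @param groups group labels, one per sample.
#' @return data.frame per taxon: group means, `stat`, `p`, `q`,
#'   `direction`.
#' @export
diff_abundance <- function(rel, groups) {
  rel <- as.matrix(rel)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  lv <- levels(groups)
  means <- t(apply(rel, 1, function(x) tapply(x, groups, mean)))
  colnames(means) <- paste0("mean_", lv)
  res <- t(apply(rel, 1, function(x) {
    if (length(unique(x)) == 1L) return(c(stat = NA_real_, p = 1))
    if (nlevels(groups) == 2) {
      w <- suppressWarnings(stats::wilcox.test(x[groups == lv[1]],
                                               x[groups == lv[2]]))
      c(stat = unname(w$statistic), p = w$p.value)
    } else {
      k <- stats::kruskal.test(x, groups)
      c(stat = unname(k$statistic), p = k$p.value)
    }
  }))
  out <- data.frame(taxon = rownames(rel), means, stat = res[, "stat"],
                    p = res[, "p"], q = bh_adjust(res[, "p"]),
                    direction = lv[max.col(means)],
                    row.names = rownames(rel), stringsAsFactors = FALSE)
  out
}

#' LDA effect-size biomarker discovery
#'
#' A linear-discriminant effect-size procedure for 2-3 classes without
#' subclass structure. Stage 1 keeps taxa passing a Kruskal-Wallis
#' (Mann-Whitney for two classes) filter at `alpha`. Stage 2 rescales
#' relative abundances to a common `[0, 1e6]` range and, over `n_boot`
#' seeded bootstrap draws (two-thirds of each class, without
#' replacement), fits Fisher's LDA (one-against-all for three classes)
#' on the retained taxa. The per-taxon effect in one draw is
#' `(|d_f| + w_f^2 |w . d|) / 2`, where `d` is the vector of rescaled
#' between-class mean differences and `w` the unit-norm discriminant
#' direction — the average of the raw mean difference and the part of
#' the discriminant projection difference attributable to the taxon.
#' The reported score is `log10(1 + effect)` averaged over draws; taxa
#' are retained when the score exceeds `lda_threshold` (the
#' conventional threshold is 2).
#'
#' @param rel taxa x samples proportions.
#' @param groups class labels (2 or 3 classes, each with >= 3 samples).
#' @param alpha stage-1 significance level.
#' @param lda_threshold minimum reported score.
#' @param n_boot bootstrap draws.
#' @param seed integer seed (mandatory).
#' @return data.frame per retained taxon: `taxon`, `enriched`
#'   (class with the highest mean), `lda_score`, `kw_p`, sorted by
#'   decreasing score. Zero rows when nothing passes.
#' @export
lda_effect_size <- function(rel, groups, alpha = 0.05, lda_threshold = 2,
                            n_boot = 30, seed) {
  if (missing(seed)) stopf("lda_effect_size requires an explicit seed")
  rel <- as.matrix(rel)
  groups <- as.factor(droplevels(as.factor(groups)))
  if (!nlevels(groups) %in% 2:3) stopf("2 or 3 classes required")
  if (any(table(groups) < 3)) stopf("every class needs >= 3 samples")

  ## stage 1: rank-test filter
  screen <- diff_abundance(rel, groups)
  cand <- rownames(screen)[!is.na(screen$p) & screen$p < alpha]
  empty <- data.frame(taxon = character(0), enriched = character(0),
                      lda_score = numeric(0), kw_p = numeric(0))
  if (length(cand) == 0) return(empty)

  ## stage 2: rescale all abundances to a common [0, 1e6] range (the
  ## range is taken over the full matrix, then candidates are extracted)
  rng <- range(rel)
  x <- rel[cand, , drop = FALSE]
  x <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) * 1e6 else x * 0
  x <- t(x)                                   # samples x taxa
  lv <- levels(groups)
  pairs <- if (nlevels(groups) == 2) list(lv) else
    lapply(lv, function(l) c(l, paste0("not_", l)))

  set.seed(seed)
  eff <- matrix(0, length(cand), n_boot, dimnames = list(cand, NULL))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(lv, function(l) {
      i <- which(groups == l)
      sample(i, max(3, floor(2 / 3 * length(i))))
    }))
    xb <- x[idx, , drop = FALSE]
    gb <- groups[idx]
    pe <- sapply(pairs, function(pr) {
      one <- if (nlevels(groups) == 2) gb == lv[1] else gb == pr[1]
      d <- colMeans(xb[one, , drop = FALSE]) -
        colMeans(xb[!one, , drop = FALSE])
      fallback <- function() {
        nd <- sqrt(sum(d^2))
        if (nd > 0) d / nd else d
      }
      w <- tryCatch({
        fit <- suppressWarnings(MASS::lda(xb, grouping = factor(one)))
        sc <- fit$scaling[, 1]
        v <- numeric(ncol(xb)); names(v) <- colnames(xb)
        nm <- rownames(fit$scaling)
        if (!is.null(nm) && all(nm %in% names(v))) v[nm] <- sc
        else if (length(sc) == length(v)) v[] <- sc
        nrm <- sqrt(sum(v^2))
        if (is.finite(nrm) && nrm > 0) v / nrm else fallback()
      }, error = function(e) fallback())
      (abs(d) + w^2 * abs(sum(w * d))) / 2
    })
    eff[, b] <- apply(as.matrix(pe), 1, max)
  }
  score <- log10(1 + rowMeans(eff))
  enriched <- screen[cand, "direction"]
  out <- data.frame(taxon = cand, enriched = enriched, lda_score = score,
                    kw_p = screen[cand, "p"], stringsAsFactors = FALSE)
  out <- out[out$lda_score > lda_threshold, , drop = FALSE]
  out[order(-out$lda_score), , drop = FALSE]
}
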