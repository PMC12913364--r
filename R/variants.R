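PREDICTION_TOOLS <- c("SIFT", "PolyPhen2_HDIV", "PolyPhen2_HVAR", "LRT",
                      "MutationTaster")
PTV_TYPES <- c("frameshift", "nonsense", "stoploss")

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p obtained by summing hypergeometric probabilities no
#' larger than that of the observed table (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(!vapply(x, is_count, logical(1))))
    stopf("cell counts must be non-negative integers")
  stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
}

#' Is a variant deleterious?
#'
#' TRUE iff the variant is protein-truncating (frameshift, nonsense or
#' stop-loss) or a missense variant with REVEL > 0.75 (strict) or at
#' least two of SIFT / PolyPhen2-HDIV / PolyPhen2-HVAR / LRT /
#' MutationTaster calling it damaging. Missing predictions never count
#' as damaging.
#'
#' @param v one row of a variant annotation data.frame (list-like with
#'   fields `vtype`, `revel` and the five tool columns).
#' @return logical.
#' @export
is_deleterious <- function(v) {
  if (v$vtype %in% PTV_TYPES) return(TRUE)
  if (!identical(as.character(v$vtype), "missense")) return(FALSE)
  revel_hit <- !is.null(v$revel) && !is.na(v$revel) && v$revel > 0.75
  calls <- unlist(v[PREDICTION_TOOLS])
  n_dmg <- sum(!is.na(calls) & calls == "damaging")
  revel_hit || n_dmg >= 2
}

#' Filter variants through the susceptibility cascade
#'
#' Retains variants that (1) show a case-control carrier frequency
#' difference at `fisher_exact_2x2` p < `alpha`; (2) lie in
#' protein-coding exons (optionally also splicing); (3) are deleterious
#' per [is_deleterious()]; and (4) are rare: gnomAD AF < `max_af`, with
#' missing AF treated as 0 (a novel variant passes the rarity filter).
#' Input order is preserved. The Fisher test operates on carrier counts
#' (subjects with at least one alternate allele); non-frameshift indels
#' do not qualify unless `include_inframe = TRUE`.
#'
#' @param variants variant annotation data.frame with columns `region`,
#'   `vtype`, `revel`, tool-call columns, `gnomad_af`, `case_carriers`,
#'   `control_carriers`, `n_cases`, `n_controls`.
#' @param alpha significance level of the frequency-difference test.
#' @param max_af gnomAD allele-frequency ceiling.
#' @param include_splicing also admit `region == "splicing"`.
#' @param include_inframe treat non-frameshift indels as qualifying types.
#' @return The qualifying subset of `variants`, with a `fisher_p` column.
#' @export
filter_variants <- function(variants, alpha = 0.05, max_af = 0.05,
                            include_splicing = FALSE,
                            include_inframe = FALSE) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0) return(cbind(variants, fisher_p = numeric(0)))
  ok_region <- variants$region == "exonic" |
    (include_splicing & variants$region == "splicing")
  vt <- variants$vtype
  del <- vapply(seq_len(nrow(variants)), function(i)
    is_deleterious(variants[i, ]), logical(1))
  if (include_inframe) del <- del | vt == "nonframeshift_indel"
  af <- variants$gnomad_af
  af[is.na(af)] <- 0
  ok_af <- af < max_af
  fp <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    fisher_exact_2x2(v$case_carriers, v$n_cases - v$case_carriers,
                     v$control_carriers, v$n_controls - v$control_carriers)
  }, numeric(1))
  out <- variants[ok_region & del & ok_af & fp < alpha, , drop = FALSE]
  out$fisher_p <- fp[ok_region & del & ok_af & fp < alpha]
  out
}

#' Classify trio inheritance origin
#'
#' @param proband,mother,father allele counts in `{0, 1, 2}`.
#' @return One of `"de_novo"`, `"maternal"`, `"paternal"`,
#'   `"biparental"`, `"uncertain"` (non-carrier proband).
#' @export
classify_trio_origin <- function(proband, mother, father) {
  g <- c(proband, mother, father)
  if (any(!g %in% 0:2)) stopf("allele counts must be in {0, 1, 2}")
  if (proband == 0) return("uncertain")
  if (mother == 0 && father == 0) return("de_novo")
  if (mother > 0 && father > 0) return("biparental")
  if (mother > 0) "maternal" else "paternal"
}

#' Per-subject pathway burden scores
#'
#' Counts, for each subject, the distinct qualifying variants in
#' `gene_set` genes that the subject carries (genotype > 0). With
#' `count_alleles = TRUE` the allele dosage is summed instead.
#'
#' @param carriers subjects x variants genotype matrix (entries 0/1/2).
#' @param qualifying character vector of qualifying variant identifiers.
#' @param gene_set character vector of pathway gene symbols.
#' @param variant_gene named character vector mapping variant id -> gene.
#' @param count_alleles sum allele dosage instead of counting variants.
#' @return Named integer vector, subject -> burden score.
#' @export
burden_scores <- function(carriers, qualifying, gene_set, variant_gene,
                          count_alleles = FALSE) {
  unknown <- setdiff(qualifying, colnames(carriers))
  if (length(unknown) > 0)
    stopf("unknown variant identifier(s): %s", paste(unknown, collapse = ", "))
  keep <- qualifying[variant_gene[qualifying] %in% gene_set]
  if (length(keep) == 0)
    return(stats::setNames(rep(0L, nrow(carriers)), rownames(carriers)))
  g <- carriers[, keep, drop = FALSE]
  sc <- if (count_alleles) rowSums(g) else rowSums(g > 0)
  stats::setNames(as.integer(sc), rownames(carriers))
}

#' Stratify by median burden and compare phenotypes
#'
#' The high stratum holds subjects whose score strictly exceeds the
#' median score (ties at the median go low); CARS and ABC are compared
#' between strata with two-sided Mann-Whitney tests and each binary GI
#' phenotype with a Fisher exact test (odds ratio reported).
#'
#' @param scores named numeric vector (subject -> burden score).
#' @param clinical clinical table with `cars`, `abc` and the binary GI
#'   flag columns; rownames are subject ids.
#' @param gi_phenotypes binary columns to test (default constipation and
#'   diarrhea).
#' @return A list of class `burden_result`: `scores`, `median`, `stratum`
#'   (factor high/low), `cars_p`, `abc_p`, `gi_tests` (data.frame with
#'   odds ratio and Fisher p) and `not_applicable` (TRUE when all scores
#'   are identical and the split is degenerate).
#' @export
stratify_and_compare <- function(scores, clinical,
                                 gi_phenotypes = c("constipation", "diarrhea")) {
  subj <- intersect(names(scores), rownames(clinical))
  if (length(subj) < 4) stopf("need at least 4 subjects with scores and phenotypes")
  scores <- scores[subj]
  cl <- clinical[subj, ]
  med <- stats::median(scores)
  stratum <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  if (length(unique(scores)) == 1L || !all(c("low", "high") %in% stratum)) {
    return(structure(list(scores = scores, median = med, stratum = stratum,
                          cars_p = NA_real_, abc_p = NA_real_,
                          gi_tests = NULL, not_applicable = TRUE),
                     class = "burden_result"))
  }
  hi <- stratum == "high"
  mw <- function(y) suppressWarnings(
    stats::wilcox.test(y[hi], y[!hi], exact = NULL)$p.value)
  gi <- do.call(rbind, lapply(gi_phenotypes, function(ph) {
    tab <- table(factor(hi, c(FALSE, TRUE)), factor(cl[[ph]], c(0, 1)))
    ft <- stats::fisher.test(tab)
    data.frame(phenotype = ph, odds_ratio = unname(ft$estimate),
               p = ft$p.value)
  }))
  structure(list(scores = scores, median = med, stratum = stratum,
                 cars_p = mw(cl$cars), abc_p = mw(cl$abc),
                 gi_tests = gi, not_applicable = FALSE),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  if (x$not_applicable) {
    cat("burden stratification not applicable (degenerate scores)\n")
    return(invisible(x))
  }
  cat(sprintf("burden median %.1f; high stratum n=%d, low n=%d\n",
              x$median, sum(x$stratum == "high"), sum(x$stratum == "low")))
  cat(sprintf("  CARS Mann-Whitney p = %.4g; ABC p = %.4g\n", x$cars_p, x$abc_p))
  if (!is.null(x$gi_tests)) print(x$gi_tests, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided (upper tail) hypergeometric test of each gene set against a
#' query gene list within a finite universe, with Benjamini-Hochberg
#' adjustment across sets. Sets are intersected with the universe first.
#'
#' @param query character vector of gene symbols (must lie in `universe`).
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of all testable gene symbols.
#' @return data.frame: set, overlap, set_size, query_size, universe_size,
#'   p, q.
#' @export
geneset_enrichment <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty gene universe")
  if (!all(query %in% universe))
    stopf("query genes outside the universe: %s",
          paste(setdiff(query, universe), collapse = ", "))
  query <- unique(query)
  res <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               query_size = length(query), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated name, description, genes.
#' @param path GMT file path.
#' @return Named list of gene symbol vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write a GMT gene-set file
#' @param collection named list of gene sets.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, "na", collection[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
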