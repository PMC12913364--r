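#' Taxon count table
#'
#' Light-weight container for a taxa x samples count matrix with
#' semicolon-delimited rank lineages (`k__...;p__...;...;g__...`) and an
#' optional sample -> group mapping. This is the basis of all microbiome
#' operations.
#'
#' @param counts non-negative integer matrix, taxa in rows (rownames are
#'   taxon identifiers), samples in columns.
#' @param lineage character vector of semicolon-delimited lineages, one
#'   per row of `counts`.
#' @param groups optional named character vector mapping sample -> group.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, lineage, groups = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (length(lineage) != nrow(counts))
    stopf("lineage length (%d) != number of taxa (%d)",
          length(lineage), nrow(counts))
  if (is.null(rownames(counts)))
    rownames(counts) <- vapply(strsplit(lineage, ";"),
                               function(x) sub("^[a-z]__", "", x[length(x)]),
                               character(1))
  if (anyDuplicated(rownames(counts))) stopf("duplicate taxon identifiers")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample identifiers")
  if (!is.null(groups)) {
    groups <- groups[colnames(counts)]
    if (anyNA(groups)) stopf("groups must cover all samples")
  }
  structure(list(counts = counts, lineage = lineage, groups = groups),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat(" (", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
           family = "f", genus = "g", species = "s")

parse_lineage <- function(lineage) {
  out <- matrix(NA_character_, length(lineage), length(RANKS),
                dimnames = list(NULL, names(RANKS)))
  parts <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    for (p in parts[[i]]) {
      pre <- substr(p, 1, 1)
      k <- match(pre, RANKS)
      val <- sub("^[a-z]__", "", p)
      if (!is.na(k) && nzchar(val)) out[i, k] <- val
    }
  }
  out
}

#' Aggregate a count table at a taxonomic rank
#'
#' Rows are summed by the lineage truncated at `rank`; taxa missing that
#' rank are pooled into `"unclassified"`. Per-sample totals are conserved.
#'
#' @param t a [count_table()].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return A [count_table()] aggregated at `rank`.
#' @export
aggregate_rank <- function(t, rank) {
  stopifnot(inherits(t, "count_table"))
  if (!rank %in% names(RANKS))
    stopf("unknown rank '%s' (must be one of %s)", rank,
          paste(names(RANKS), collapse = ", "))
  k <- match(rank, names(RANKS))
  tab <- parse_lineage(t$lineage)
  key <- apply(tab[, seq_len(k), drop = FALSE], 1, function(r) {
    if (anyNA(r)) "unclassified" else
      paste(sprintf("%s__%s", RANKS[seq_len(k)], r), collapse = ";")
  })
  agg <- rowsum(t$counts, group = key, reorder = TRUE)
  lin <- rownames(agg)
  name <- ifelse(lin == "unclassified", "unclassified",
                 sub("^.*__", "", lin))
  ## disambiguate repeated leaf names across lineages
  name <- make.unique(name, sep = "_")
  rownames(agg) <- name
  count_table(agg, lineage = lin, groups = t$groups)
}

#' Convert counts to per-sample relative abundances
#'
#' @param t a [count_table()] or a non-negative taxa x samples matrix.
#' @return A matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(t) {
  m <- if (inherits(t, "count_table")) t$counts else as.matrix(t)
  tot <- colSums(m)
  if (any(tot == 0)) {
    nm <- colnames(m) %||% as.character(seq_len(ncol(m)))
    stopf("sample(s) with zero total count: %s",
          paste(nm[tot == 0], collapse = ", "))
  }
  sweep(m, 2, tot, "/")
}

#' Read / write abundance tables
#'
#' Tab-separated, first column `lineage` holding the semicolon rank
#' convention, remaining columns samples.
#' @param path file path.
#' @param groups optional named group vector passed to [count_table()].
#' @return [count_table()] for `read_abundance`; invisibly `path` for
#'   `write_abundance`.
#' @export
read_abundance <- function(path, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "lineage")
    stopf("%s: first column must be 'lineage' (got '%s')", path, names(df)[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stopf("%s: non-numeric or missing abundance values", path)
  count_table(m, lineage = df$lineage, groups = groups)
}

#' @rdname read_abundance
#' @param t a [count_table()].
#' @export
write_abundance <- function(t, path) {
  stopifnot(inherits(t, "count_table"))
  df <- data.frame(lineage = t$lineage, t$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
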