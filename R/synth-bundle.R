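#' Simulate a complete synthetic multi-omics cohort
#'
#' Runs the four generators in a fixed order (clinical, variants,
#' microbiome, metabolome), each on its own seed stream derived from the
#' configuration seed, and assembles the bundle together with the
#' ground-truth ledger used by parameter-recovery tests. Identical
#' configurations produce byte-identical bundles.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_bundle`: a list with `clinical`,
#'   `variants`, `carriers`, `trios`, `counts` (a [count_table()]),
#'   `intensities`, `config` and `truth` (qualifying variants, true
#'   burden, differential taxa, metabolite module partition, ...).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  clinical <- gen_clinical(config)
  gv <- gen_variants(config, clinical)
  gm <- gen_microbiome(config, clinical)
  gx <- gen_metabolome(config, clinical)
  truth <- c(gv$truth, gm$truth, gx$truth)
  stopifnot(identical(colnames(gm$counts$counts), clinical$subject),
            all(rownames(gx$intensities) %in% clinical$subject),
            identical(rownames(gv$carriers), clinical$subject))
  structure(list(clinical = clinical, variants = gv$variants,
                 carriers = gv$carriers, trios = gv$trios,
                 counts = gm$counts, intensities = gx$intensities,
                 config = config, truth = truth),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synthetic multi-omics bundle (seed %d)\n", x$config$seed))
  cat(sprintf("  clinical: %d subjects | variants: %d | taxa: %d | metabolites: %d x %d samples\n",
              nrow(x$clinical), nrow(x$variants), nrow(x$counts$counts),
              ncol(x$intensities), nrow(x$intensities)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Writes `clinical.tsv`, `variants.tsv`, `carriers.tsv`, `trios.tsv`,
#' `counts.tsv` (taxa x samples, first column the semicolon lineage),
#' `intensities.csv` (samples x metabolites) and `truth.json`. All files
#' are UTF-8 with deterministic row order.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name, rn = FALSE) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
    p
  }
  paths <- c(
    tsv(bundle$clinical, "clinical.tsv"),
    tsv(bundle$variants, "variants.tsv"),
    tsv(data.frame(subject = rownames(bundle$carriers), bundle$carriers,
                   check.names = FALSE), "carriers.tsv"),
    tsv(bundle$trios, "trios.tsv"))
  paths <- c(paths, write_abundance(bundle$counts, file.path(dir, "counts.tsv")))
  ip <- file.path(dir, "intensities.csv")
  utils::write.csv(data.frame(subject = rownames(bundle$intensities),
                              bundle$intensities, check.names = FALSE),
                   ip, row.names = FALSE, quote = FALSE)
  tp <- file.path(dir, "truth.json")
  truth <- bundle$truth
  truth$module_factors <- NULL
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, ip, tp))
}
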