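## Mucin-pathway gene set used by the planted burden design
MUC_GENES <- c("MUC2", "MUC4", "MUC5B", "MUC6", "MUC12", "MUC16", "MUC17", "MUC21")

#' Generate synthetic variant annotations, carriage and trios
#'
#' Emits a mixture of *qualifying* variants (protein-truncating or
#' consensus-damaging missense, gnomAD AF < 0.05, exonic) in mucin-pathway
#' genes and non-qualifying decoys (benign predictions, common alleles,
#' non-exonic or synonymous records, and a few damaging rare variants
#' outside the pathway). Case carriage of qualifying variants is driven by
#' a per-subject true burden coupled to CARS through a Gaussian copula:
#' the latent burden normal score is correlated with the rank-normal CARS
#' score of the cases at a Pearson level calibrated (by an internal
#' Monte-Carlo attenuation step) so that the *Spearman* correlation of the
#' discretised burden with CARS matches `burden_cars_rho`. Controls carry
#' qualifying variants at the low background rate `bg_carrier_rate`, so
#' qualifying variants are genuinely case-enriched and survive their own
#' case-control frequency test. Trio genotypes reproduce the reported
#' inheritance mix: eleven de novo plus one maternally inherited variant.
#'
#' @param config a [synth_config()].
#' @param clinical output of [gen_clinical()] for the same config.
#' @return A list with `variants` (annotation data.frame, one row per
#'   variant, including per-arm carrier counts), `carriers` (subjects x
#'   variants genotype matrix with entries 0/1/2), `trios` (one row per
#'   trio: proband/mother/father allele counts and the true origin), and
#'   `truth` (qualifying variant ids, pathway genes, per-subject true
#'   burden).
#' @export
gen_variants <- function(config, clinical) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(clinical))
  if (abs(config$burden_cars_rho) > 1) stopf("burden_cars_rho outside [-1, 1]")
  set.seed(config$seed + 2L)
  n_qual <- 9L
  if (config$n_variants < n_qual + 1L)
    stopf("n_variants must be at least %d", n_qual + 1L)

  qual <- data.frame(
    gene = c("MUC6", "MUC6", "MUC6", "MUC6", "MUC6", "MUC17", "MUC17",
             "MUC21", "MUC2"),
    cytoband = c(rep("11p15.5", 5), "7q22.1", "7q22.1", "6p21.33", "11p15.5"),
    region = "exonic",
    vtype = c(rep("missense", 7), "frameshift", "missense"),
    gnomad_af = c(0, 1.878e-05, 5.531e-06, 0, 0.0065, 0.0225, 0.0312,
                  0.0081, 0.001),
    revel = c(0.82, 0.88, 0.91, 0.79, 0.8, 0.84, 0.77, NA, 0.82),
    n_damaging_tools = c(4L, 5L, 5L, 3L, 4L, 4L, 3L, 0L, 4L),
    stringsAsFactors = FALSE)

  n_decoy <- config$n_variants - n_qual
  decoy_kind <- rep(c("benign_missense", "common_damaging", "non_exonic",
                      "synonymous", "offtarget_damaging", "inframe_indel"),
                    length.out = n_decoy)
  decoy_gene <- ifelse(decoy_kind %in% c("benign_missense", "inframe_indel"),
                       sample(MUC_GENES, n_decoy, replace = TRUE),
                       sprintf("GENE%03d", seq_len(n_decoy)))
  decoy <- data.frame(
    gene = decoy_gene, cytoband = "1q21.1",
    region = ifelse(decoy_kind == "non_exonic",
                    sample(c("intronic", "UTR", "intergenic"), n_decoy, TRUE),
                    "exonic"),
    vtype = ifelse(decoy_kind == "synonymous", "synonymous",
                   ifelse(decoy_kind == "inframe_indel", "nonframeshift_indel",
                          "missense")),
    gnomad_af = ifelse(decoy_kind == "common_damaging",
                       stats::runif(n_decoy, 0.06, 0.3),
                       stats::runif(n_decoy, 0, 0.04)),
    revel = ifelse(decoy_kind %in% c("common_damaging", "offtarget_damaging", "non_exonic"),
                   stats::runif(n_decoy, 0.76, 0.95),
                   stats::runif(n_decoy, 0.05, 0.5)),
    n_damaging_tools = ifelse(decoy_kind %in% c("common_damaging", "offtarget_damaging", "non_exonic"),
                              sample(2:5, n_decoy, TRUE),
                              sample(0:1, n_decoy, TRUE)),
    stringsAsFactors = FALSE)
  decoy$revel[decoy_kind %in% c("synonymous", "inframe_indel")] <- NA

  variants <- rbind(qual, decoy)
  variants$variant_id <- sprintf("v%03d", seq_len(nrow(variants)))
  variants$transcript <- sprintf("NM_%06d", 100000L + seq_len(nrow(variants)))
  variants$cdna_change <- sprintf("c.%dA>G", sample(100:9000, nrow(variants)))
  variants$aa_change <- sprintf("p.X%dY", sample(30:2900, nrow(variants)))
  tools <- c("SIFT", "PolyPhen2_HDIV", "PolyPhen2_HVAR", "LRT", "MutationTaster")
  for (k in seq_along(tools)) {
    variants[[tools[k]]] <- ifelse(
      variants$vtype == "missense",
      ifelse(k <= variants$n_damaging_tools, "damaging", "benign"), NA)
  }

  ## per-subject true burden over the qualifying variants
  is_case <- clinical$group == "ASD"
  n <- nrow(clinical)
  burden <- integer(n)
  rho <- config$burden_cars_rho
  rho_star <- if (rho == 0) 0 else {
    ## two Monte-Carlo correction passes for the discretisation
    ## attenuation of the copula (realized Spearman of the binomial
    ## burden is below the latent level)
    clamp <- function(x) max(min(x, 0.99), -0.99)
    realized <- function(r) {
      zc <- stats::rnorm(1e5); w <- stats::rnorm(1e5)
      b <- stats::qbinom(stats::pnorm(r * zc + sqrt(1 - r^2) * w), n_qual,
                         config$qual_carrier_rate)
      suppressWarnings(stats::cor(b, zc, method = "spearman"))
    }
    r_star <- clamp(2 * sin(pi * rho / 6))
    for (pass in 1:2) {
      s <- realized(r_star)
      if (abs(s) < 1e-6) break
      r_star <- clamp(r_star * rho / s)
    }
    r_star
  }
  zc_case <- rank_normal(clinical$cars[is_case])
  w <- stats::rnorm(sum(is_case))
  u_case <- stats::pnorm(rho_star * zc_case + sqrt(1 - rho_star^2) * w)
  burden[is_case] <- stats::qbinom(u_case, n_qual, config$qual_carrier_rate)
  burden[!is_case] <- stats::rbinom(sum(!is_case), n_qual, config$bg_carrier_rate)

  carriers <- matrix(0L, n, nrow(variants),
                     dimnames = list(clinical$subject, variants$variant_id))
  qual_ids <- variants$variant_id[seq_len(n_qual)]
  for (i in seq_len(n)) {
    if (burden[i] > 0) {
      pick <- sample(qual_ids, burden[i])
      carriers[i, pick] <- ifelse(stats::runif(burden[i]) < 0.05, 2L, 1L)
    }
  }
  decoy_rate <- stats::runif(n_decoy, 0.02, 0.15)
  for (j in seq_len(n_decoy)) {
    hit <- stats::runif(n) < decoy_rate[j]
    carriers[hit, n_qual + j] <- ifelse(stats::runif(sum(hit)) < 0.05, 2L, 1L)
  }

  variants$case_carriers <- colSums(carriers[is_case, , drop = FALSE] > 0)
  variants$control_carriers <- colSums(carriers[!is_case, , drop = FALSE] > 0)
  variants$n_cases <- sum(is_case)
  variants$n_controls <- sum(!is_case)
  variants$n_damaging_tools <- NULL
  rownames(variants) <- variants$variant_id

  ## trios: 12 probands, 11 de novo + 1 maternal (reported inheritance mix)
  ord <- order(-burden[is_case], clinical$subject[is_case])
  probands <- clinical$subject[is_case][ord][1:12]
  trio_var <- vapply(probands, function(s) {
    carried <- qual_ids[carriers[s, qual_ids] > 0]
    if (length(carried) > 0) carried[1] else qual_ids[1]
  }, character(1))
  trios <- data.frame(subject = probands, variant = trio_var,
                      proband = 1L, mother = 0L, father = 0L,
                      origin = "de_novo", stringsAsFactors = FALSE)
  trios$mother[12] <- 1L
  trios$origin[12] <- "maternal"

  truth <- list(qualifying_variants = qual_ids, pathway_genes = MUC_GENES,
                true_burden = stats::setNames(burden, clinical$subject))
  list(variants = variants, carriers = carriers, trios = trios, truth = truth)
}
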