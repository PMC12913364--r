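#' Configuration for the synthetic multi-omics cohort
#'
#' Builds the single configuration object consumed by all `gen_*()`
#' generators and by [simulate_cohort()]. Defaults emulate the statistical
#' structure of a 51-case / 51-control childhood ASD gut-brain cohort:
#' clinical phenotype prevalences follow the published cohort table,
#' the planted diarrhea effect on CARS is 3.47 points and the planted
#' insomnia effect on ABC is 14.82 points, the mucin-pathway burden score
#' is coupled to CARS among cases at Spearman 0.32 through a Gaussian
#' copula, cases carry a planted Shannon-diversity deficit, per-group
#' latent correlation blocks drive co-occurrence networks with a higher
#' negative-association fraction in controls, and metabolite modules are
#' planted as latent factors correlated with clinical traits.
#'
#' @param seed integer seed; identical configurations (including seed)
#'   reproduce byte-identical bundles.
#' @param n_cases,n_controls cohort arm sizes (>= 2).
#' @param n_taxa number of genus-level taxa simulated.
#' @param n_metabolites number of metabolite features simulated.
#' @param n_variants total variant records (qualifying plus decoys).
#' @param burden_cars_rho target Spearman correlation between the true
#'   mucin-pathway burden and CARS within cases, in `[-1, 1]`.
#' @param diarrhea_beta planted CARS shift (points) for diarrhea.
#' @param insomnia_beta planted ABC shift (points) for insomnia.
#' @param shannon_shift planted Shannon alpha-diversity deficit in cases
#'   (natural-log units).
#' @param depth sequencing depth per sample (multinomial total, >= 100).
#' @param lognormal_sigma log-normal sd of latent taxon base abundances.
#' @param network_negedge_ratio named vector, per-group target fraction of
#'   negative latent associations, e.g. `c(ASD = 0.10, TD = 0.30)`.
#' @param module_spec data.frame with columns `size`, `within_cor`,
#'   `trait` (clinical column or NA) and `trait_cor` describing planted
#'   metabolite co-expression modules.
#' @param prevalences list with elements `case` and `control`: named
#'   vectors of binary-phenotype prevalences in `[0, 1]`.
#' @param n_metab_cases,n_metab_controls size of the metabolomics
#'   sub-cohort (first subjects of each arm).
#' @param diff_taxa data.frame of planted differential taxa (columns
#'   `name`, `fc`, `where`); `where` is `"ASD"` (case shift), `"ASD_D"`,
#'   `"ASD_noD"` or `"TD"`.
#' @param n_diff_up,n_diff_down number of planted up/down-regulated
#'   metabolites (case vs control) and `diff_fc` their raw-scale fold
#'   change.
#' @param diff_fc raw-scale fold change of planted differential metabolites.
#' @param qual_carrier_rate per-variant carriage probability of
#'   qualifying variants among cases; the default plants the strong
#'   case enrichment that the study's reported per-variant significance
#'   levels imply.
#' @param bg_carrier_rate per-variant background carriage probability of
#'   qualifying variants among controls.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_cases = 51L, n_controls = 51L,
                         n_taxa = 150L, n_metabolites = 1200L,
                         n_variants = 60L,
                         burden_cars_rho = 0.32,
                         diarrhea_beta = 3.47,
                         insomnia_beta = 14.82,
                         shannon_shift = 0.3,
                         depth = 20000L,
                         lognormal_sigma = 1.5,
                         network_negedge_ratio = c(ASD = 0.10, TD = 0.30),
                         module_spec = default_module_spec(),
                         prevalences = default_prevalences(),
                         n_metab_cases = 25L, n_metab_controls = 25L,
                         diff_taxa = default_diff_taxa(),
                         n_diff_up = 20L, n_diff_down = 68L, diff_fc = 4,
                         qual_carrier_rate = 0.25,
                         bg_carrier_rate = 0.02) {
  if (!is_count(n_cases) || !is_count(n_controls) || n_cases < 2 || n_controls < 2)
    stopf("n_cases and n_controls must be integers >= 2")
  if (!is_count(seed %% 2^31)) stopf("seed must be an integer")
  for (r in c(burden_cars_rho, module_spec$trait_cor[!is.na(module_spec$trait_cor)]))
    if (abs(r) > 1) stopf("correlations must lie in [-1, 1]")
  if (any(module_spec$within_cor >= 1) || any(module_spec$within_cor < 0))
    stopf("within-module correlations must lie in [0, 1)")
  if (sum(module_spec$size) > n_metabolites)
    stopf("module sizes sum (%d) exceeds n_metabolites (%d)",
          sum(module_spec$size), n_metabolites)
  pv <- unlist(prevalences)
  if (any(pv < 0 | pv > 1)) stopf("prevalences must lie in [0, 1]")
  if (depth < 100) stopf("depth must be >= 100 reads (got %s)", depth)
  if (n_metab_cases > n_cases || n_metab_controls > n_controls)
    stopf("metabolomics sub-cohort cannot exceed the cohort arms")
  cfg <- list(
    seed = as.integer(seed), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), n_taxa = as.integer(n_taxa),
    n_metabolites = as.integer(n_metabolites), n_variants = as.integer(n_variants),
    burden_cars_rho = burden_cars_rho, diarrhea_beta = diarrhea_beta,
    insomnia_beta = insomnia_beta, shannon_shift = shannon_shift,
    depth = as.integer(depth), lognormal_sigma = lognormal_sigma,
    network_negedge_ratio = network_negedge_ratio,
    module_spec = module_spec, prevalences = prevalences,
    n_metab_cases = as.integer(n_metab_cases),
    n_metab_controls = as.integer(n_metab_controls),
    diff_taxa = diff_taxa, n_diff_up = as.integer(n_diff_up),
    n_diff_down = as.integer(n_diff_down), diff_fc = diff_fc,
    qual_carrier_rate = qual_carrier_rate,
    bg_carrier_rate = bg_carrier_rate)
  class(cfg) <- "synth_config"
  cfg
}

#' Default planted metabolite module specification
#'
#' Nine modules (mirroring the module count reported for the emulated
#' study) with sizes 120 down to 30; the largest ("turquoise" after size
#' ranking) is coupled to diarrhea at r = -0.5, two further modules to
#' diarrhea at -0.49 and +0.41, and one to CARS at +0.40.
#' @export
default_module_spec <- function() {
  data.frame(
    size = c(120L, 90L, 70L, 60L, 50L, 45L, 40L, 35L, 30L),
    within_cor = 0.7,
    trait = c("diarrhea", "diarrhea", NA, NA, "diarrhea", "cars", NA, NA, NA),
    trait_cor = c(-0.50, -0.49, NA, NA, 0.41, 0.40, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Default clinical phenotype prevalences
#'
#' Case prevalences follow the published cohort table (constipation
#' 36/51, diarrhea 18/51, insomnia 18/51, hypersomnia 11/51, lower
#' urinary tract symptoms 21/51, repetitive behaviors 42/51, male
#' 36/51). Control prevalences are typical paediatric background rates.
#' @export
default_prevalences <- function() {
  list(
    case = c(male = 36 / 51, constipation = 36 / 51, diarrhea = 18 / 51,
             insomnia = 18 / 51, hypersomnia = 11 / 51, luts = 21 / 51,
             repetitive = 42 / 51),
    control = c(male = 36 / 51, constipation = 0.15, diarrhea = 0.10,
                insomnia = 0.10, hypersomnia = 0.05, luts = 0.08,
                repetitive = 0.02))
}

#' Default planted differential taxa
#'
#' Fold changes are case-vs-control on the latent relative-abundance
#' scale; `where = "ASD"` shifts all cases, subgroup labels shift only
#' that subgroup (used by the three-class biomarker design).
#' @export
default_diff_taxa <- function() {
  data.frame(
    name = c("Faecalibacterium", "Bacteroides", "Bifidobacterium",
             "Prevotella", "Aeromonas", "Coprococcus",
             "Megamonas", "Escherichia_Shigella",
             "Lachnospiraceae_NK4A136_group", "Lactobacillus"),
    fc = c(0.2, 0.5, 3, 2, 5, 1 / 3, 4, 2.5, 0.4, 2.5),
    where = c("ASD", "ASD", "ASD", "ASD", "ASD", "ASD",
              "ASD_D", "ASD_D", "ASD", "ASD_noD"),
    stringsAsFactors = FALSE)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic cohort configuration\n")
  cat(sprintf("  seed %d | %d cases + %d controls | %d taxa, depth %d | %d metabolites | %d variants\n",
              x$seed, x$n_cases, x$n_controls, x$n_taxa, x$depth,
              x$n_metabolites, x$n_variants))
  cat(sprintf("  planted: burden~CARS rho %.2f, diarrhea beta %.2f, insomnia beta %.2f, Shannon shift %.2f\n",
              x$burden_cars_rho, x$diarrhea_beta, x$insomnia_beta, x$shannon_shift))
  invisible(x)
}
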