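#' Run the full multi-omics pipeline on a synthetic cohort
#'
#' Chains simulate -> variant burden -> microbiome profiling -> networks
#' -> metabolite modules -> integration, writing every stage's artifacts
#' under `outdir` plus a `summary.json` holding the headline statistics
#' and the full parameter metadata. All stochastic stages are seeded
#' from the configuration seed, so re-running the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config a [synth_config()].
#' @param outdir output directory.
#' @param n_perm permutations for PERMANOVA.
#' @param n_perm_protest permutations for PROTEST.
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_all <- function(config = synth_config(), outdir, n_perm = 999,
                    n_perm_protest = 9999, quiet = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("simulating cohort (seed %d)...", seed)
  bundle <- simulate_cohort(config)
  write_bundle(bundle, file.path(outdir, "synthetic"))
  clinical <- bundle$clinical

  ## ---- variant burden -------------------------------------------------
  say("variant filtering and burden scoring...")
  qual <- filter_variants(bundle$variants)
  vg <- stats::setNames(bundle$variants$gene, bundle$variants$variant_id)
  burden <- burden_scores(bundle$carriers, qual$variant_id, MUC_GENES, vg)
  clinical$gene_score <- burden[rownames(clinical)]
  strat <- stratify_and_compare(burden, clinical)
  trios <- bundle$trios
  trios$classified <- vapply(seq_len(nrow(trios)), function(i)
    classify_trio_origin(trios$proband[i], trios$mother[i], trios$father[i]),
    character(1))
  universe <- unique(bundle$variants$gene)
  collection <- list(MUC_pathway = MUC_GENES)
  enr <- geneset_enrichment(unique(qual$gene), collection, universe)
  utils::write.table(qual, file.path(outdir, "qualifying_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(subject = names(burden), burden = burden,
                                stratum = as.character(strat$stratum[names(burden)])),
                     file.path(outdir, "burden.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(median = strat$median, cars_p = strat$cars_p,
                            abc_p = strat$abc_p, gi_tests = strat$gi_tests,
                            trio_origins = as.list(table(trios$classified)),
                            enrichment = enr),
                       file.path(outdir, "burden_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## ---- microbiome profile ---------------------------------------------
  say("microbiome profiling...")
  ct <- bundle$counts
  rel <- relative_abundance(ct)
  alpha <- alpha_diversity(ct)
  bc <- bray_curtis(rel)
  ord <- pcoa(bc, k = 2)
  perm <- permanova(bc, ct$groups, n_perm = n_perm, seed = seed + 11L)
  da <- diff_abundance(rel, ct$groups)
  lefse2 <- lda_effect_size(rel, ct$groups, seed = seed + 12L)
  lefse3 <- lda_effect_size(rel, clinical$subgroup, seed = seed + 13L)
  utils::write.table(alpha, file.path(outdir, "alpha.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.matrix(bc), file.path(outdir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(ord$coordinates, file.path(outdir, "pcoa.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(perm, file.path(outdir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(da, file.path(outdir, "diff_abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lefse2, file.path(outdir, "lefse.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lefse3, file.path(outdir, "lefse_subgroup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- co-occurrence networks -----------------------------------------
  say("co-occurrence networks...")
  net_stats <- list()
  for (g in unique(ct$groups)) {
    net <- build_network(rel[, ct$groups == g, drop = FALSE])
    topo <- topology(net)
    nc <- natural_connectivity(net)
    rob <- robustness(net, mode = "random", n_repeat = 10, seed = seed + 21L)
    net_stats[[g]] <- c(topo[c("n_nodes", "n_edges", "connectance",
                               "average_degree", "negative_ratio")],
                        natural_connectivity = nc)
    utils::write.table(net$edges, file.path(outdir, sprintf("network_%s_edges.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rob, file.path(outdir, sprintf("network_%s_robustness.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_graphml(net, file.path(outdir, sprintf("network_%s.graphml", g)))
  }
  jsonlite::write_json(net_stats, file.path(outdir, "network_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## ---- metabolite modules ---------------------------------------------
  say("metabolite module detection...")
  intens <- bundle$intensities
  mgroups <- clinical[rownames(intens), "group"]
  pre <- preprocess_intensities(intens, top_k = 1000)
  volc <- volcano(intens, mgroups)
  vip <- pls_da_vip(pre, mgroups)
  sft <- pick_soft_threshold(pre)
  tom <- tom_similarity(adjacency_matrix(pre, sft$power))
  partition <- detect_modules(tom, min_size = 30)
  eig <- eigenprofiles(pre, partition)
  mt <- module_trait(eig, clinical)
  utils::write.table(volc, file.path(outdir, "volcano.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sft$table, file.path(outdir, "scale_free_fit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(metabolite = names(partition),
                                color = as.character(partition),
                                vip = vip[names(partition)]),
                     file.path(outdir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(eig$profiles, file.path(outdir, "eigenprofiles.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(cbind(module = rownames(mt$r), as.data.frame(mt$r)),
                     file.path(outdir, "module_trait.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- integration -----------------------------------------------------
  say("multi-omics integration...")
  msub <- rownames(intens)
  bc_mic <- bray_curtis(rel[, msub, drop = FALSE])
  diffm <- rownames(volc)[volc$call != "ns"]
  if (length(diffm) < 3) diffm <- rownames(volc)[order(volc$p)][1:50]
  mm <- intens[, diffm, drop = FALSE]
  mm <- apply(mm, 2, function(x) {
    r <- range(x); if (diff(r) > 0) (x - r[1]) / diff(r) else x * 0
  })
  rownames(mm) <- msub
  bc_met <- bray_curtis(t(mm))
  nm1 <- nmds_ordination(bc_mic, seed = seed + 31L)
  nm2 <- nmds_ordination(bc_met, seed = seed + 32L)
  proc <- procrustes_protest(nm1$points, nm2$points,
                             n_perm = n_perm_protest, seed = seed + 33L)
  constraints <- data.frame(gene_score = clinical$gene_score,
                            cars = clinical$cars, abc = clinical$abc,
                            row.names = rownames(clinical))
  rda <- db_rda(bc, constraints)
  ## association assessed within cases (TD severity scores carry no signal)
  gsa <- gene_score_association(clinical[clinical$group == "ASD", ],
                                alpha[clinical$group == "ASD", ])
  ols_cars <- multivariable_ols(
    clinical$cars[clinical$group == "ASD"],
    clinical[clinical$group == "ASD",
             c("diarrhea", "constipation", "sex", "age", "income")])
  ols_abc <- multivariable_ols(
    clinical$abc[clinical$group == "ASD"],
    clinical[clinical$group == "ASD",
             c("insomnia", "hypersomnia", "sex", "age", "income")])
  jsonlite::write_json(list(m2 = proc$m2, p = proc$p, n_perm = proc$n_perm),
                       file.path(outdir, "procrustes.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(data.frame(axis = names(rda$eigenvalues),
                                eig = rda$eigenvalues),
                     file.path(outdir, "dbrda.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(cbind(model = "CARS", ols_cars$coefficients),
                           cbind(model = "ABC", ols_abc$coefficients)),
                     file.path(outdir, "regression_forest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("gbomics")),
    seed = seed,
    parameters = list(n_perm = n_perm, n_perm_protest = n_perm_protest,
                      rho_min = 0.6, fdr = 0.05, min_prevalence = 0.2,
                      top_k = 1000, min_module_size = 30,
                      lda_threshold = 2, alpha = 0.05, max_af = 0.05),
    burden = list(median = strat$median, cars_p = strat$cars_p,
                  abc_p = strat$abc_p,
                  n_qualifying = nrow(qual)),
    permanova = perm[c("f", "p")],
    network = net_stats,
    modules = list(n_modules = length(setdiff(unique(partition), "grey")),
                   power = sft$power,
                   sizes = as.list(unclass(attr(partition, "sizes")))),
    module_trait_r = as.data.frame(mt$r),
    procrustes = list(m2 = proc$m2, p = proc$p),
    dbrda_constrained_prop = rda$constrained_prop,
    gene_score = gsa,
    regression = list(
      diarrhea_beta = ols_cars$coefficients$beta[
        ols_cars$coefficients$term == "diarrhea"],
      insomnia_beta = ols_abc$coefficients$beta[
        ols_abc$coefficients$term == "insomnia"]))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
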