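# gbomics

Integrated gene-microbiome-metabolome analysis for case-control
gut-brain axis studies in children with autism spectrum disorder (ASD).

Cohort studies of the gut-brain axis in ASD combine whole-exome
variant screens, 16S rRNA community profiling, and untargeted plasma
metabolomics, and then ask whether host genetic defects — in
particular rare deleterious variants in mucin (MUC) pathway genes that
maintain the intestinal mucus barrier — track with gastrointestinal
symptoms, clinical severity, and a restructured gut ecosystem.
`gbomics` packages that entire analysis chain as tested, reusable R
functions, together with a fully seeded synthetic-cohort generator
whose planted effect sizes give every stage a ground truth for
parameter-recovery testing.

## What it computes

* **Variant burden** — the susceptibility filter cascade (two-sided
  Fisher exact test on carrier counts with p < 0.05; protein-coding
  exons only; protein-truncating or consensus-damaging missense with
  REVEL > 0.75 or at least 2/5 damaging tool calls; gnomAD AF < 5%),
  trio-origin classification, the per-subject pathway burden score
  `b_i = #{qualifying variants in the gene set carried by i}`, median
  stratification with Mann-Whitney phenotype comparison, and local
  hypergeometric gene-set enrichment with BH adjustment.
* **Microbiome profile** — rank aggregation, relative abundance, alpha
  diversity (Shannon `H = -sum p ln p`, Pielou evenness `H / ln S`,
  Gini-Simpson, bias-corrected Chao1, ACE), Bray-Curtis / PCoA /
  seeded PERMANOVA, per-taxon rank tests with BH, and an LDA
  effect-size biomarker procedure (Kruskal-Wallis filter, [0, 1e6]
  rescaling, bootstrapped linear discriminant, `log10` score with the
  conventional > 2 threshold) for 2- and 3-class designs.
* **Network ecology** — per-group signed Spearman co-occurrence
  networks, connectance `2E / n(n-1)`, average degree, negative-edge
  ratio, and natural connectivity
  `ln((1/n) sum_i exp(lambda_i))` with random and degree-ordered
  node-removal robustness curves.
* **Metabolite modules** — top-1000 variable metabolites, soft
  threshold at scale-free fit R^2 >= 0.85, unsigned adjacency ->
  topological overlap matrix, tree cut with minimum module size 30,
  module eigenprofiles, module-trait Spearman grids, plus volcano
  screening and PLS-DA VIP.
* **Integration** — NMDS, symmetric Procrustes with PROTEST
  permutation significance, distance-based RDA, Spearman correlation
  grids, and multivariable OLS with t-based Wald intervals.
* **Synthetic cohorts** — `synth_config()` / `simulate_cohort()` plant
  a 51 + 51 cohort with a copula-coupled burden-severity association
  (Spearman 0.32 among cases), clinical effects (diarrhea -> CARS
  +3.47, insomnia -> ABC +14.82), a Shannon-diversity deficit,
  differential taxa, group-specific negative-association fractions,
  and trait-coupled metabolite modules.

## Worked example

```r
library(gbomics)

cfg <- synth_config(seed = 1)        # the default study conditions
bundle <- simulate_cohort(cfg)
#> synthetic multi-omics bundle (seed 1)
#>   clinical: 102 subjects | variants: 60 | taxa: 150 | metabolites: 1200 x 50 samples

## variant filter cascade and mucin-pathway burden
qual <- filter_variants(bundle$variants)
nrow(qual)                           # 8 qualifying variants survive
variant_gene <- setNames(bundle$variants$gene, bundle$variants$variant_id)
score <- burden_scores(bundle$carriers, qual$variant_id,
                       bundle$truth$pathway_genes, variant_gene)
stratify_and_compare(score, bundle$clinical)
#> burden median 1.0; high stratum n=32, low n=70
#>   CARS Mann-Whitney p = 1.022e-12; ABC p = 1.067e-09
#>     phenotype odds_ratio            p
#>  constipation   5.472764 0.0002092107
#>      diarrhea   5.853119 0.0003414117

## gene score tracks severity among cases (planted Spearman 0.32)
cases <- bundle$clinical$group == "ASD"
cor(score[cases], bundle$clinical$cars[cases], method = "spearman")
#> [1] 0.551   (single-seed estimate; the across-seed mean sits near 0.32)

## community structure differs between groups
rel <- relative_abundance(bundle$counts)
permanova(bray_curtis(rel), bundle$counts$groups, n_perm = 999, seed = 8)
#> $f [1] 6.34   $p [1] 0.001
```

The high-burden stratum shows markedly higher CARS/ABC scores and
about 5-to-6-fold odds of gastrointestinal symptoms — the planted
genotype-phenotype coupling recovered through the full filter
cascade — and PERMANOVA rejects community equality between the ASD
and TD arms at its permutation floor.

`run_all(cfg, "outdir")` chains every stage (synthetic data ->
variants -> microbiome -> networks -> metabolome -> integration) and
writes per-stage TSV/JSON artifacts plus a `summary.json` with the
headline statistics and full parameter metadata; `inst/scripts/pipeline.R`
is a command-line wrapper over it.

## Documentation

The methods vignette (`vignettes/gbomics-methods.Rmd`) documents the
generative models, every tunable parameter with its default and
rationale, the numerical conventions, and the limits of what the
synthetic experiments demonstrate.
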