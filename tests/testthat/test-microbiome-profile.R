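toy_table <- function() {
  counts <- matrix(c(3, 4, 2, 0,
                     1, 0, 5, 2,
                     2, 2, 2, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, sprintf("s%d", 1:4)))
  lineage <- c("k__Bacteria;p__Firmicutes;c__C;o__O;f__F;g__GenA",
               "k__Bacteria;p__Firmicutes;c__C;o__O;f__F;g__GenB",
               "k__Bacteria;p__Bacteroidota;c__C2;o__O2;f__F2;g__GenC")
  count_table(counts, lineage)
}

test_that("rank aggregation is additive and conserves sample totals", {
  ct <- toy_table()
  ph <- aggregate_rank(ct, "phylum")
  expect_equal(nrow(ph$counts), 2)
  firm <- ph$counts[grep("Firmicutes", ph$lineage), ]
  expect_equal(unname(firm), unname(ct$counts[1, ] + ct$counts[2, ]))
  expect_equal(colSums(ph$counts), colSums(ct$counts))
  ## genus-level aggregation of a genus table keeps every row
  ge <- aggregate_rank(ct, "genus")
  expect_equal(nrow(ge$counts), 3)
  expect_equal(colSums(ge$counts), colSums(ct$counts))
  expect_error(aggregate_rank(ct, "strain"), "unknown rank")
})

test_that("aggregation pools lineages missing the rank as unclassified", {
  ct <- count_table(matrix(c(5, 1), 2, dimnames = list(NULL, "s1")),
                    c("k__Bacteria;p__Firmicutes", "k__Bacteria"))
  ph <- aggregate_rank(ct, "phylum")
  expect_true("unclassified" %in% rownames(ph$counts))
  expect_equal(sum(ph$counts), 6)
})

test_that("aggregation conserves totals on random tables", {
  set.seed(3)
  for (i in 1:20) {
    nt <- sample(5:20, 1)
    phyla <- sample(c("A", "B", "C"), nt, TRUE)
    lin <- sprintf("k__Bacteria;p__%s;c__c;o__o;f__f;g__g%02d", phyla, 1:nt)
    m <- matrix(rpois(nt * 4, 5), nt, dimnames = list(NULL, sprintf("s%d", 1:4)))
    ct <- count_table(m, lin)
    for (rk in c("phylum", "family")) {
      expect_equal(colSums(aggregate_rank(ct, rk)$counts), colSums(m))
    }
  }
})

test_that("relative abundance normalizes every sample to one", {
  expect_equal(unname(relative_abundance(matrix(c(2, 2), 2, 1))[, 1]),
               c(0.5, 0.5))
  expect_equal(unname(relative_abundance(matrix(c(0, 7), 2, 1))[, 1]), c(0, 1))
  set.seed(4)
  m <- matrix(rpois(60, 9) + 1, 10, 6, dimnames = list(NULL, sprintf("s%d", 1:6)))
  expect_equal(unname(colSums(relative_abundance(m))), rep(1, 6),
               tolerance = 1e-12)
  m[, 3] <- 0
  expect_error(relative_abundance(m), "s3")
})

test_that("alpha diversity matches closed forms", {
  ## uniform over four taxa
  a <- alpha_diversity(matrix(c(5, 5, 5, 5), 4, 1,
                              dimnames = list(NULL, "s1")))
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$evenness, 1, tolerance = 1e-12)
  expect_equal(a$simpson, 0.75, tolerance = 1e-12)
  ## single taxon
  b <- alpha_diversity(matrix(c(9, 0), 2, 1, dimnames = list(NULL, "s1")))
  expect_equal(b$shannon, 0)
  expect_equal(b$simpson, 0)
  expect_equal(b$evenness, 0)
  expect_equal(b$observed, 1)
  ## direct formula evaluation for counts (5, 3, 2)
  cc <- alpha_diversity(matrix(c(5, 3, 2), 3, 1, dimnames = list(NULL, "s1")))
  expect_equal(cc$shannon,
               -sum(c(.5, .3, .2) * log(c(.5, .3, .2))), tolerance = 1e-9)
  ## bias-corrected Chao1 on S = 5, F1 = 2, F2 = 1
  d <- alpha_diversity(matrix(c(1, 1, 2, 3, 10), 5, 1,
                              dimnames = list(NULL, "s1")))
  expect_equal(d$chao1, 5 + 2 * 1 / (2 * 2), tolerance = 1e-9)  # 5.5
  expect_gte(d$chao1, d$observed)
  expect_error(alpha_diversity(matrix(0, 2, 1)), "positive")
})

test_that("Shannon strictly increases when a count is split", {
  base <- c(6, 4)
  split <- c(6, 2, 2)
  h <- function(x) { p <- x / sum(x); -sum(p * log(p)) }
  expect_gt(h(split), h(base))
  expect_lt(abs(alpha_diversity(matrix(base, 2, 1,
                                       dimnames = list(NULL, "s")))$shannon -
                  h(base)), 1e-12)
})

test_that("alpha indices are invariant to taxon ordering", {
  set.seed(5)
  m <- matrix(rpois(40, 6), 10, 4, dimnames = list(NULL, sprintf("s%d", 1:4)))
  a1 <- alpha_diversity(m)
  a2 <- alpha_diversity(m[sample(10), ])
  expect_equal(a1, a2)
})

test_that("Bray-Curtis matches hand values and is a semi-metric", {
  x <- matrix(c(1, 2, 2, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  d <- bray_curtis(x)
  expect_equal(as.numeric(d), 0.6)   # (|1-2| + |2-0|) / (3 + 2)
  same <- matrix(c(3, 1, 3, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- matrix(c(5, 0, 0, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  ## the triangle inequality may fail (semi-metric): witness triple
  tri <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  dm <- as.matrix(bray_curtis(tri))
  expect_gt(dm["x", "y"], dm["x", "z"] + dm["z", "y"])
})

test_that("PCoA embeds collinear points and preserves duplicates", {
  ## three points on a line at 0, 1, 3
  d <- stats::dist(matrix(c(0, 1, 3), 3, 1))
  p <- pcoa(d)
  ax1 <- p$coordinates[, 1]
  expect_equal(abs(diff(ax1)), c(1, 2), tolerance = 1e-9)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)
  ## Euclidean input has no meaningful negative eigenvalues
  set.seed(6)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    ev <- pcoa(stats::dist(X))$eigenvalues
    expect_gt(min(ev), -1e-9 * max(abs(ev)))
  }
  ## duplicated sample lands on identical coordinates
  X <- matrix(rnorm(10), 5, 2)
  X <- rbind(X, X[3, ])
  pd <- pcoa(stats::dist(X))
  expect_equal(pd$coordinates[3, ], pd$coordinates[6, ], tolerance = 1e-9)
})

test_that("PERMANOVA agrees with the exhaustive enumeration oracle", {
  ## two tight groups of three, far apart
  set.seed(8)
  X <- rbind(matrix(rnorm(9, 0, .1), 3), matrix(rnorm(9, 5, .1), 3))
  rownames(X) <- sprintf("s%d", 1:6)
  d <- stats::dist(X)
  g <- rep(c("A", "B"), each = 3)
  obs <- permanova_f_oracle(d, g)
  ## enumerate all 20 assignments of 3 + 3 labels
  combs <- utils::combn(6, 3)
  fs <- apply(combs, 2, function(idx) {
    gg <- rep("B", 6); gg[idx] <- "A"
    permanova_f_oracle(d, gg)
  })
  p_exact <- mean(fs >= obs - 1e-12)   # 2 of 20 splits reach the observed F
  expect_equal(p_exact, 0.1)
  fit <- permanova(d, g, n_perm = 999, seed = 1)
  expect_equal(fit$f, obs, tolerance = 1e-8)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(fit$p - p_exact), 2 * mc_se + 1e-3)
})

test_that("PERMANOVA validates groups and is seed-reproducible", {
  set.seed(9)
  d <- stats::dist(matrix(rnorm(12 * 3), 12))
  g <- rep(c("A", "B"), each = 6)
  expect_error(permanova(d, c(rep("A", 11), "B"), seed = 1), "size 1")
  expect_error(permanova(d, rep("A", 12), seed = 1), "2 groups")
  expect_error(permanova(d, g), "seed")
  f1 <- permanova(d, g, n_perm = 199, seed = 5)
  f2 <- permanova(d, g, n_perm = 199, seed = 5)
  expect_identical(f1, f2)
})

test_that("identical group compositions give a null PERMANOVA result", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    m <- matrix(runif(12 * 15), 15, 12,
                dimnames = list(NULL, sprintf("s%d", 1:12)))
    d <- bray_curtis(m)
    permanova(d, rep(c("A", "B"), 6), n_perm = 199, seed = s)$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("differential abundance handles nulls, zeros, and matches BH", {
  set.seed(10)
  m <- matrix(rpois(30 * 16, 10), 30, 16,
              dimnames = list(sprintf("t%02d", 1:30), sprintf("s%d", 1:16)))
  g <- rep(c("A", "B"), each = 8)
  ## identical groups: no small q values
  da <- diff_abundance(m, g)
  expect_true(all(da$q > 0.2))
  ## all-zero taxon gets p = 1 by convention
  m[1, ] <- 0
  da2 <- diff_abundance(m, g)
  expect_equal(da2["t01", "p"], 1)
  ## BH column reproduces the literal step-up definition
  expect_equal(unname(da2$q), bh_oracle(da2$p), tolerance = 1e-12)
})

test_that("LDA effect size scores a lone discriminative taxon near its oracle", {
  set.seed(11)
  n <- 10
  taxon <- c(runif(n, 0.09, 0.11), runif(n, 0, 0.005))
  other <- runif(2 * n, 0.45, 0.55)
  rel <- rbind(disc = taxon, flat = other)
  colnames(rel) <- sprintf("s%02d", 1:(2 * n))
  g <- rep(c("A", "B"), each = n)
  res <- lda_effect_size(rel, g, seed = 3)
  expect_true("disc" %in% res$taxon)
  expect_false("flat" %in% res$taxon)
  expect_equal(res$enriched[res$taxon == "disc"], "A")
  ## with one retained feature the discriminant is the feature itself, so
  ## the effect is the rescaled mean difference
  rng <- range(rel)
  d_exp <- abs(mean(taxon[1:n]) - mean(taxon[-(1:n)])) / diff(rng) * 1e6
  expect_lt(abs(res$lda_score[res$taxon == "disc"] - log10(1 + d_exp)), 0.2)
  expect_gt(res$lda_score[res$taxon == "disc"], 2)
})

test_that("LDA effect size validates inputs and filters null taxa", {
  set.seed(12)
  rel <- matrix(runif(5 * 12), 5, 12,
                dimnames = list(sprintf("t%d", 1:5), sprintf("s%d", 1:12)))
  g <- rep(c("A", "B"), each = 6)
  ## identically distributed taxa rarely pass stage 1; never reported
  res <- lda_effect_size(rel, g, alpha = 1e-6, seed = 1)
  expect_equal(nrow(res), 0)
  expect_error(lda_effect_size(rel, rep(c("A", "B", "C", "D"), 3), seed = 1),
               "classes")
  expect_error(lda_effect_size(rel[, 1:4], c("A", "A", "B", "B"), seed = 1),
               ">= 3 samples")
  expect_error(lda_effect_size(rel, g), "seed")
})
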