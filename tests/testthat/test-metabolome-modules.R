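test_that("preprocessing ranks variance like a naive two-pass oracle", {
  set.seed(1)
  m <- matrix(rexp(30 * 50, 1 / 100), 30, 50,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("m%02d", 1:50)))
  m[, 7] <- 42                           # constant metabolite
  pre <- preprocess_intensities(m, top_k = 20)
  lx <- log1p(m)
  naive_var <- vapply(seq_len(ncol(lx)), function(j) {
    mu <- sum(lx[, j]) / nrow(lx)
    sum((lx[, j] - mu)^2) / (nrow(lx) - 1)
  }, numeric(1))
  expect_setequal(attr(pre, "selected"),
                  colnames(m)[order(naive_var, decreasing = TRUE)[1:20]])
  expect_false("m07" %in% attr(pre, "selected"))  # constant ranks last
  ## top_k = all is the identity selection (log scale)
  all_pre <- preprocess_intensities(m, top_k = 50)
  expect_equal(all_pre, lx, ignore_attr = TRUE)
  expect_identical(attr(all_pre, "selected"), colnames(m))
  expect_warning(preprocess_intensities(m, top_k = 60), "clamped")
})

test_that("volcano calls planted directions and handles degenerate cases", {
  set.seed(2)
  n <- 8
  m <- matrix(rlnorm(2 * n * 30, 5, 0.3), 2 * n, 30,
              dimnames = list(sprintf("s%02d", 1:(2 * n)),
                              sprintf("met%02d", 1:30)))
  g <- rep(c("ASD", "TD"), each = n)
  ## identical groups: zero calls
  expect_true(all(volcano(m, g)$call == "ns"))
  ## metabolite present only in cases is called up
  m2 <- m
  m2[g == "TD", 1] <- 0
  m2[g == "ASD", 1] <- rlnorm(n, 7, 0.2)
  v <- volcano(m2, g)
  expect_equal(v["met01", "call"], "up")
  expect_true(all(v$q >= v$p))
  expect_error(volcano(m[1:5, ], c("ASD", "ASD", "ASD", "TD", "TD")),
               ">= 3 samples")
  expect_error(volcano(m, rep("A", 2 * n)), "two groups")
})

test_that("planted fold-change metabolites are recovered with correct sign", {
  hits <- vapply(1:10, function(s) {
    cfg <- quick_cfg(seed = s)   # plants 10 up, 15 down at fold change 4
    cl <- gen_clinical(cfg)
    gx <- gen_metabolome(cfg, cl)
    grp <- cl[rownames(gx$intensities), "group"]
    v <- volcano(gx$intensities, grp)
    up_ok <- mean(v[gx$truth$up_metabolites, "call"] == "up")
    dn_ok <- mean(v[gx$truth$down_metabolites, "call"] == "down")
    (up_ok + dn_ok) / 2
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("VIP satisfies its algebraic identity and flags separators", {
  set.seed(3)
  m <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("m%02d", 1:25)))
  g <- rep(c("A", "B"), each = 20)
  vip <- pls_da_vip(m, g)
  expect_equal(mean(vip^2), 1, tolerance = 1e-8)
  ## pure noise: no metabolite dominates
  expect_lt(max(vip), 3)
  ## a single perfectly separating metabolite gets the maximal VIP
  m[, 5] <- ifelse(g == "A", 5, -5) + rnorm(40, 0, 0.01)
  vip2 <- pls_da_vip(m, g)
  expect_equal(names(which.max(vip2)), "m05")
})

test_that("soft-threshold choice follows the documented rule", {
  ## full-scale hub-structured co-expression attains the criterion
  cfg <- synth_config(seed = 6)
  cl <- gen_clinical(cfg)
  gx <- gen_metabolome(cfg, cl)
  pre <- preprocess_intensities(gx$intensities, 1000)
  sft <- suppressWarnings(pick_soft_threshold(pre))
  expect_true(sft$reached)
  expect_true(any(!is.na(sft$table$r2) & sft$table$r2 >= 0.85))
  ## chosen-power rule against an exhaustive scan of the table
  ok <- with(sft$table, which(!is.na(r2) & r2 >= 0.85))
  expect_equal(sft$power, sft$table$power[ok[1]])
  ## a permissive threshold always selects the smallest assessable power
  low <- suppressWarnings(pick_soft_threshold(pre, r2_min = -1))
  valid <- which(!is.na(low$table$r2))
  expect_equal(low$power, low$table$power[valid[1]])
  expect_error(pick_soft_threshold(pre[, 1:5]), ">= 20")
})

test_that("TOM matches hand values and a triple-loop oracle", {
  ## complete unit adjacency saturates at 1
  A1 <- matrix(1, 5, 5); diag(A1) <- 0
  expect_true(all(abs(tom_similarity(A1) - 1) < 1e-12))
  ## three nodes, a12 = a13 = 0.5, a23 = 0
  A2 <- matrix(0, 3, 3)
  A2[1, 2] <- A2[2, 1] <- 0.5
  A2[1, 3] <- A2[3, 1] <- 0.5
  expect_equal(tom_similarity(A2)[1, 2], 0.5, tolerance = 1e-12)
  ## brute-force oracle on random adjacencies
  set.seed(5)
  for (rep in 1:3) {
    n <- 15
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- runif(n * (n - 1) / 2)
    A <- A + t(A)
    tom <- tom_similarity(A)
    k <- colSums(A)
    oracle <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      oracle[i, j] <- oracle[j, i] <-
        (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    expect_equal(tom, oracle, tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(c(0, 2, 2, 0), 2)), "\\[0, 1\\]")
})

test_that("tree cut recovers planted blocks exactly", {
  set.seed(6)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, p) sapply(seq_len(p), function(i)
    0.9 * f + sqrt(1 - 0.81) * rnorm(n))
  m <- cbind(block(f1, 45), block(f2, 35))
  colnames(m) <- sprintf("m%02d", 1:80)
  tom <- tom_similarity(adjacency_matrix(m, 6))
  part <- detect_modules(tom, min_size = 30)
  truth <- rep(c(1, 2), c(45, 35))
  expect_equal(length(setdiff(unique(part), "grey")), 2)
  expect_equal(ari(truth, part), 1)
  ## the largest module is labelled turquoise
  expect_equal(names(which.max(table(part))), "turquoise")
})

test_that("tiny inputs go all grey and partitions are order-stable", {
  small <- matrix(runif(100), 10, 10)
  expect_true(all(detect_modules(small * 0 + diag(10), min_size = 30) == "grey"))
  set.seed(7)
  n <- 30
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- cbind(sapply(1:35, function(i) 0.9 * f1 + 0.45 * rnorm(n)),
             sapply(1:35, function(i) 0.9 * f2 + 0.45 * rnorm(n)),
             matrix(rnorm(n * 20), n))
  colnames(m) <- sprintf("m%02d", 1:90)
  tom <- tom_similarity(adjacency_matrix(m, 6))
  p1 <- detect_modules(tom, min_size = 30)
  perm <- sample(ncol(tom))
  p2 <- detect_modules(tom[perm, perm], min_size = 30)
  expect_equal(ari(p1[colnames(tom)], p2[colnames(tom)]), 1)
})

test_that("eigenprofiles satisfy orientation, norm, and an iterative oracle", {
  set.seed(8)
  n <- 25
  prof <- rnorm(n)
  m <- sapply(1:32, function(i) prof * runif(1, 0.5, 2) + rnorm(n, 0, 1e-6))
  colnames(m) <- sprintf("m%02d", 1:32)
  rownames(m) <- sprintf("s%02d", 1:n)
  part <- stats::setNames(rep("turquoise", 32), colnames(m))
  eig <- eigenprofiles(m, part)
  e <- eig$profiles[, "turquoise"]
  expect_equal(sum(e^2), 1, tolerance = 1e-9)                  # unit norm
  expect_gt(stats::cor(e, prof), 0.999)                        # the profile
  expect_gt(eig$var_explained[["turquoise"]], 0.999)
  ## negating all members flips the orientation
  eig_neg <- eigenprofiles(-m, part)
  expect_equal(unname(eig_neg$profiles[, 1]), unname(-e), tolerance = 1e-6)
  ## power-iteration oracle on a generic module
  m2 <- matrix(rnorm(n * 32), n, 32, dimnames = dimnames(m))
  e2 <- eigenprofiles(m2, part)$profiles[, 1]
  S <- tcrossprod(scale(m2))
  v <- rnorm(n)
  for (i in 1:500) { v <- S %*% v; v <- v / sqrt(sum(v^2)) }
  expect_equal(abs(sum(v * e2)), 1, tolerance = 1e-8)
  expect_error(eigenprofiles(m, stats::setNames(rep("grey", 32), colnames(m))),
               "non-grey")
})

test_that("module-trait correlation handles exact and degenerate traits", {
  set.seed(9)
  prof <- matrix(rnorm(40), 20, 2,
                 dimnames = list(sprintf("s%02d", 1:20), c("turquoise", "blue")))
  cl <- data.frame(diarrhea = rank(prof[, 1]), constipation = 1,
                   insomnia = rbinom(20, 1, .5),
                   cars = rnorm(20), abc = rnorm(20),
                   row.names = rownames(prof))
  mt <- module_trait(prof, cl)
  expect_equal(mt$r["turquoise", "diarrhea"], 1)
  expect_true(is.na(mt$r["turquoise", "constipation"]))   # constant trait
  expect_true(all(mt$r >= -1 & mt$r <= 1, na.rm = TRUE))
  expect_error(module_trait(prof[1:3, ], cl[1:3, ]), "overlap")
})

test_that("default pipeline recovers the planted module count", {
  nmods <- vapply(1:25, function(s) {
    cfg <- synth_config(seed = s)
    cl <- gen_clinical(cfg)
    gx <- gen_metabolome(cfg, cl)
    pre <- preprocess_intensities(gx$intensities, 1000)
    sft <- suppressWarnings(pick_soft_threshold(pre))
    tom <- tom_similarity(adjacency_matrix(pre, sft$power))
    part <- detect_modules(tom, min_size = 30)
    length(setdiff(unique(part), "grey"))
  }, numeric(1))
  ## planted 9 modules, allowing +-1 for grey absorption
  expect_gte(mean(abs(nmods - 9) <= 1), 0.8)
})
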