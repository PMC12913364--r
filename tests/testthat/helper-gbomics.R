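## shared fixtures and small oracles, built in code

## a scaled-down configuration for fast unit tests
quick_cfg <- function(seed = 1, ...) {
  synth_config(
    seed = seed, n_taxa = 120, depth = 5000, n_metabolites = 400,
    module_spec = data.frame(
      size = c(60L, 40L, 30L), within_cor = 0.7,
      trait = c("diarrhea", NA, NA), trait_cor = c(-0.5, NA, NA),
      stringsAsFactors = FALSE),
    n_diff_up = 10, n_diff_down = 15, ...)
}

## adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2)); r <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2)); n <- choose(sum(tab), 2)
  (s - r * cc / n) / ((r + cc) / 2 - r * cc / n)
}

## independent Fisher oracle: full enumeration of the hypergeometric
## support with fixed margins, summing probabilities <= observed
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## PERMANOVA pseudo-F from a distance matrix and labels (textbook
## sums-of-squared-distances partition)
permanova_f_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss <- function(idx) sum(d[idx, idx]^2) / (2 * length(idx))
  ss_t <- ss(seq_len(n))
  ss_w <- sum(vapply(split(seq_len(n), groups), ss, numeric(1)))
  a <- length(unique(groups))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

## symmetric Procrustes M^2 oracle (center, scale to unit sum of
## squares, SVD of cross-product)
procrustes_m2_oracle <- function(X, Y) {
  cs <- function(Z) {
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Z / sqrt(sum(Z^2))
  }
  X <- cs(as.matrix(X)); Y <- cs(as.matrix(Y))
  1 - sum(svd(crossprod(X, Y))$d)^2
}

## literal Benjamini-Hochberg step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
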