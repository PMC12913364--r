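PHYLA <- c("Firmicutes", "Bacteroidota", "Proteobacteria", "Actinobacteriota",
           "Patescibacteria", "Verrucomicrobiota")

#' Generate the synthetic genus-level microbiome count table
#'
#' Counts are drawn from a log-normal relative-abundance model with
#' multinomial sampling at the configured depth. Latent per-sample
#' log-abundances are `mu_t + e_ts` with `mu_t ~ N(0, lognormal_sigma^2)`
#' fixed across samples; `e` carries a per-group block-correlation
#' structure (8 blocks of 12 filler taxa, within-block latent correlation
#' 0.8) in which a group-specific fraction of members load negatively —
#' the flipped fraction `f` solves `2 f (1 - f) = q` for the configured
#' negative-association target `q`, driving the co-occurrence networks.
#' Planted differential taxa receive `log(fc)` shifts in their target
#' (sub)group. The case Shannon deficit is produced by truncating each
#' case sample to its top `m` taxa (fewer effectively present taxa); `m`
#' is calibrated by an internal Monte-Carlo scan of the latent model so
#' the expected TD - ASD Shannon difference matches `shannon_shift`.
#'
#' @param config a [synth_config()].
#' @param clinical output of [gen_clinical()] for the same config.
#' @return A list: `counts` (a [count_table()], samples in clinical
#'   order, groups attached) and `truth` (planted differential taxa,
#'   truncation level `m_kept`, block membership and per-group sign
#'   flips).
#' @export
gen_microbiome <- function(config, clinical) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(clinical))
  if (config$depth < 100) stopf("depth < 100 reads is too sparse")
  set.seed(config$seed + 3L)
  nt <- config$n_taxa
  dt <- config$diff_taxa
  if (nrow(dt) + 12L > nt)
    stopf("n_taxa too small for the planted design (need >= %d)", nrow(dt) + 12L)

  filler <- sprintf("Genus%03d", seq_len(nt - nrow(dt)))
  taxa <- c(dt$name, filler)
  phy <- sample(PHYLA, nt, replace = TRUE)
  lineage <- sprintf("k__Bacteria;p__%s;c__%s_c;o__%s_o;f__%s_f;g__%s",
                     phy, phy, phy, phy, taxa)

  mu <- stats::rnorm(nt, 0, config$lognormal_sigma)
  names(mu) <- taxa
  ## give planted differential taxa mid-to-high base abundance so they are
  ## detectable at the configured depth
  mu[dt$name] <- stats::rnorm(nrow(dt), 1, 0.5)

  ## correlation blocks over filler taxa (up to 8 blocks of 12)
  block_size <- 12L
  n_block <- min(8L, length(filler) %/% block_size)
  block_taxa <- filler[seq_len(n_block * block_size)]
  block_of <- rep(seq_len(n_block), each = block_size)
  names(block_of) <- block_taxa
  qr <- config$network_negedge_ratio
  flips <- lapply(qr, function(q) {
    q <- min(max(q, 0), 0.5)
    f <- (1 - sqrt(1 - 2 * q)) / 2
    s <- rep(1, length(block_taxa))
    for (b in seq_len(n_block)) {
      idx <- which(block_of == b)
      k <- round(f * length(idx))
      if (k > 0) s[idx[seq_len(k)]] <- -1
    }
    stats::setNames(s, block_taxa)
  })

  groups <- clinical$group
  subgroups <- clinical$subgroup
  n <- nrow(clinical)
  rho_b <- 0.8   # within-block latent correlation

  latent_logabund <- function(i) {
    g <- groups[i]
    e <- stats::rnorm(nt)
    zb <- stats::rnorm(n_block)
    s <- flips[[g]] %||% flips[[1]]
    eb <- sqrt(rho_b) * s * zb[block_of] + sqrt(1 - rho_b) * e[seq_along(block_of)]
    e[seq_along(block_of)] <- eb
    la <- mu + e
    names(la) <- taxa
    for (j in seq_len(nrow(dt))) {
      w <- dt$where[j]
      hit <- (w == "ASD" && g == "ASD") || (w == subgroups[i])
      if (hit) la[dt$name[j]] <- la[dt$name[j]] + log(dt$fc[j])
    }
    la
  }

  ## calibrate case truncation level m for the Shannon deficit
  m_kept <- nt
  if (config$shannon_shift > 0) {
    probe <- replicate(100, {
      la <- mu + stats::rnorm(nt)
      p <- exp(la); p / sum(p)
    })
    h_trunc <- function(p, m) {
      q <- sort(p, decreasing = TRUE)[seq_len(m)]
      q <- q / sum(q)
      -sum(q * log(q))
    }
    grid <- unique(pmin(seq(10L, nt, by = 2L), nt))
    h_full <- mean(apply(probe, 2, function(p) -sum(p * log(p))))
    hm <- vapply(grid, function(m) mean(apply(probe, 2, h_trunc, m = m)),
                 numeric(1))
    m_kept <- grid[which.min(abs((h_full - hm) - config$shannon_shift))]
  }

  counts <- matrix(0L, nt, n, dimnames = list(taxa, clinical$subject))
  for (i in seq_len(n)) {
    la <- latent_logabund(i)
    p <- exp(la - max(la)); p <- p / sum(p)
    if (groups[i] == "ASD" && m_kept < nt) {
      keep <- order(p, decreasing = TRUE)[seq_len(m_kept)]
      p[-keep] <- 0
      p <- p / sum(p)
    }
    counts[, i] <- stats::rmultinom(1, config$depth, p)
  }

  ct <- count_table(counts, lineage = lineage,
                    groups = stats::setNames(groups, clinical$subject))
  truth <- list(diff_taxa = dt, m_kept = m_kept, block_of = block_of,
                flips = flips)
  list(counts = ct, truth = truth)
}
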