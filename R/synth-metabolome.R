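#' Generate the synthetic metabolite intensity matrix
#'
#' Factor model on the metabolomics sub-cohort (by default the first 25
#' subjects of each arm). Each planted module m has one latent factor
#' `f_m = a t + sqrt(1 - a^2) z` where `t` is the standardized configured
#' trait (binary traits 0/1-standardized) and `a` its configured
#' correlation; member metabolites are `x = sqrt(w) f_m + sqrt(1 - w) e`
#' so that the expected within-module pairwise correlation is `w`.
#' Remaining metabolites are independent noise; a configured subset is
#' differentially shifted between arms by `log(diff_fc)`. Log-intensities
#' are `mu_j + s_j x` with `mu_j ~ N(10, 1)` and dispersion `s_j = 1.3`
#' for module members versus `1.0` for noise (co-regulated metabolites
#' vary more, which also keeps planted modules inside the top-variable
#' selection), exponentiated to positive intensities.
#'
#' @param config a [synth_config()].
#' @param clinical output of [gen_clinical()] for the same config.
#' @return A list: `intensities` (samples x metabolites matrix, rownames
#'   are the sub-cohort subject ids), and `truth` (module partition as an
#'   integer vector with 0 = unassigned, the module trait couplings, and
#'   the planted up/down metabolite ids).
#' @export
gen_metabolome <- function(config, clinical) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(clinical))
  ms <- config$module_spec
  if (nrow(ms) > 0 && any(ms$within_cor >= 1))
    stopf("within-module correlation must be < 1")
  set.seed(config$seed + 4L)

  cases <- clinical$subject[clinical$group == "ASD"][seq_len(config$n_metab_cases)]
  ctrls <- clinical$subject[clinical$group == "TD"][seq_len(config$n_metab_controls)]
  sub <- clinical[c(cases, ctrls), ]
  n <- nrow(sub); p <- config$n_metabolites
  met <- sprintf("met%04d", seq_len(p))

  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(sub$subject, met))
  partition <- integer(p); names(partition) <- met
  disp <- rep(1, p)

  trait_vec <- function(name) {
    v <- switch(name, cars = sub$cars, abc = sub$abc, sub[[name]])
    if (is.null(v)) stopf("unknown module trait '%s'", name)
    as.numeric(scale(as.numeric(v)))
  }

  idx <- 0L
  module_factors <- NULL
  if (nrow(ms) > 0) {
    module_factors <- matrix(NA_real_, n, nrow(ms))
    for (m in seq_len(nrow(ms))) {
      size <- ms$size[m]; wc <- ms$within_cor[m]
      a <- if (is.na(ms$trait_cor[m])) 0 else ms$trait_cor[m]
      f <- if (a != 0) {
        t <- trait_vec(ms$trait[m])
        a * t + sqrt(1 - a^2) * stats::rnorm(n)
      } else stats::rnorm(n)
      module_factors[, m] <- f
      cols <- idx + seq_len(size)
      ## heterogeneous loadings (hub structure): mean loading sqrt(wc), so
      ## the mean pairwise within-module correlation is wc
      lam <- stats::runif(size, max(sqrt(wc) - 0.12, 0.05),
                          min(sqrt(wc) + 0.12, 0.99))
      x[, cols] <- sweep(matrix(f, n, size), 2, lam, "*") +
        sweep(x[, cols, drop = FALSE], 2, sqrt(1 - lam^2), "*")
      partition[cols] <- m
      disp[cols] <- 1.3
      idx <- idx + size
    }
  }

  ## planted differential metabolites among the noise features
  noise_cols <- which(partition == 0L)
  n_up <- min(config$n_diff_up, length(noise_cols))
  n_dn <- min(config$n_diff_down, length(noise_cols) - n_up)
  up <- noise_cols[seq_len(n_up)]
  dn <- noise_cols[n_up + seq_len(n_dn)]
  is_case <- sub$group == "ASD"
  shift <- log(config$diff_fc)
  if (n_up > 0) x[is_case, up] <- x[is_case, up] + shift
  if (n_dn > 0) x[is_case, dn] <- x[is_case, dn] - shift

  mu <- stats::rnorm(p, 10, 1)
  intensities <- exp(sweep(sweep(x, 2, disp, "*"), 2, mu, "+"))

  truth <- list(partition = partition,
                module_spec = ms,
                module_factors = module_factors,
                up_metabolites = met[up], down_metabolites = met[dn])
  list(intensities = intensities, truth = truth)
}
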