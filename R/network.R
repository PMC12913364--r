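#' Build a signed co-occurrence network for one group
#'
#' Taxa present in fewer than `min_prevalence` of the samples (or
#' constant across samples, whose rank correlation is undefined) are
#' dropped; remaining pairs are scored by Spearman correlation with the
#' tie-corrected t approximation for p, Benjamini-Hochberg across all
#' pairs, and an edge is kept when `q < fdr` and `|rho| >= rho_min`.
#' Edge sign is the sign of rho.
#'
#' @param rel taxa x samples abundance matrix for a single group
#'   (>= 5 samples).
#' @param rho_min minimum absolute Spearman correlation.
#' @param fdr BH q-value threshold.
#' @param min_prevalence minimum fraction of samples with non-zero
#'   abundance.
#' @return Object of class `co_network`: `nodes` (retained taxa),
#'   `edges` (data.frame u, v, rho, q, sign), `params`, `n_samples`.
#' @export
build_network <- function(rel, rho_min = 0.6, fdr = 0.05,
                          min_prevalence = 0.2) {
  rel <- as.matrix(rel)
  ns <- ncol(rel)
  if (ns < 5) stopf("need >= 5 samples to build a network (got %d)", ns)
  keep <- rowMeans(rel > 0) >= min_prevalence
  keep <- keep & apply(rel, 1, function(x) length(unique(x)) > 1)
  m <- rel[keep, , drop = FALSE]
  nodes <- rownames(m)
  nn <- length(nodes)
  edges <- data.frame(u = character(0), v = character(0), rho = numeric(0),
                      q = numeric(0), sign = integer(0))
  if (nn >= 2) {
    rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    ut <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[ut]
    ## tie-corrected large-sample t approximation
    tstat <- r * sqrt((ns - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = ns - 2)
    p[abs(r) >= 1] <- 0
    q <- bh_adjust(p)
    sel <- q < fdr & abs(r) >= rho_min
    edges <- data.frame(u = nodes[ut[sel, 1]], v = nodes[ut[sel, 2]],
                        rho = r[sel], q = q[sel],
                        sign = as.integer(sign(r[sel])),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 params = list(rho_min = rho_min, fdr = fdr,
                               min_prevalence = min_prevalence),
                 n_samples = ns),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign < 0)))
  invisible(x)
}

## 0/1 (or |rho|-weighted) symmetric adjacency of a co_network
adjacency_of <- function(net, weighted = FALSE) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    w <- if (weighted) abs(net$edges$rho) else 1
    A[cbind(net$edges$u, net$edges$v)] <- w
    A[cbind(net$edges$v, net$edges$u)] <- w
  }
  A
}

#' Topological summary of a co-occurrence network
#'
#' @param net a [build_network()] result.
#' @return list: `n_nodes`, `n_edges`, `connectance` (`2E / (n (n - 1))`),
#'   `average_degree` (`2E / n`), `negative_ratio` (0 with a `zero_edges`
#'   flag when the graph is empty).
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "co_network"))
  n <- length(net$nodes)
  if (n < 2) stopf("topology needs >= 2 nodes")
  e <- nrow(net$edges)
  list(n_nodes = n, n_edges = e,
       connectance = 2 * e / (n * (n - 1)),
       average_degree = 2 * e / n,
       negative_ratio = if (e == 0) 0 else sum(net$edges$sign < 0) / e,
       zero_edges = e == 0)
}

#' Natural connectivity of a network
#'
#' `ln((1/n) sum_i exp(lambda_i))` over the eigenvalues of the (by
#' default unweighted) symmetric adjacency matrix, computed with an
#' overflow-safe log-sum-exp. The empty graph has natural connectivity 0.
#'
#' @param net a [build_network()] result or a symmetric adjacency matrix.
#' @param weighted use `|rho|` edge weights instead of 0/1 adjacency.
#' @return numeric scalar.
#' @export
natural_connectivity <- function(net, weighted = FALSE) {
  A <- if (inherits(net, "co_network")) adjacency_of(net, weighted) else {
    A <- as.matrix(net)
    stopifnot(isSymmetric(unname(A)))
    A
  }
  n <- nrow(A)
  if (n == 0) return(0)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(lam)
}

#' Natural-connectivity robustness under node removal
#'
#' Nodes are removed cumulatively in steps of `step_fraction * n`, either
#' in seeded random orders (repeated `n_repeat` times; mean and sd
#' reported) or in a single degree-descending order (ties broken by node
#' identifier for determinism). Natural connectivity is recomputed on the
#' induced subgraph at each step.
#'
#' @param net a [build_network()] result (>= 10 nodes).
#' @param mode `"random"` or `"degree"`.
#' @param step_fraction fraction of nodes removed per step.
#' @param n_repeat number of random orders (random mode).
#' @param seed integer seed (mandatory in random mode).
#' @return data.frame of class `robustness_curve`: `fraction_removed`,
#'   `nc_mean`, `nc_sd` (0 in degree mode).
#' @export
robustness <- function(net, mode = c("random", "degree"),
                       step_fraction = 0.05, n_repeat = 20, seed = NULL) {
  stopifnot(inherits(net, "co_network"))
  mode <- match.arg(mode)
  n <- length(net$nodes)
  if (n < 10) stopf("robustness needs >= 10 nodes (got %d)", n)
  A <- adjacency_of(net)
  fractions <- seq(0, 1, by = step_fraction)
  n_remove <- unique(pmin(round(fractions * n), n))
  fractions <- n_remove / n

  nc_after <- function(ord, k) {
    keep <- setdiff(seq_len(n), ord[seq_len(k)])
    if (length(keep) == 0) return(0)
    natural_connectivity(A[keep, keep, drop = FALSE])
  }
  if (mode == "degree") {
    deg <- colSums(A > 0)
    ord <- order(-deg, net$nodes)
    nc <- vapply(n_remove, function(k) nc_after(ord, k), numeric(1))
    out <- data.frame(fraction_removed = fractions, nc_mean = nc, nc_sd = 0)
  } else {
    if (is.null(seed)) stopf("random-mode robustness requires a seed")
    set.seed(seed)
    curves <- replicate(n_repeat, {
      ord <- sample.int(n)
      vapply(n_remove, function(k) nc_after(ord, k), numeric(1))
    })
    out <- data.frame(fraction_removed = fractions,
                      nc_mean = rowMeans(curves),
                      nc_sd = apply(curves, 1, stats::sd))
  }
  class(out) <- c("robustness_curve", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' Export a co-occurrence network to GraphML
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "co_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v", "rho", "q", "sign")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
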