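#' @keywords internal
"_PACKAGE"

## formatted stop/warning helpers used across the package
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## overflow-safe log(mean(exp(x)))
log_mean_exp <- function(x) {
  if (length(x) == 0L) return(0)
  m <- max(x)
  m + log(mean(exp(x - m)))
}

## rank-based inverse normal transform (Blom offset); ties share ranks
rank_normal <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

## Benjamini-Hochberg with NA passthrough
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
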