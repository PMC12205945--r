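#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values p(1) <= ... <= p(m), reject all
#' hypotheses up to the largest i with p(i) <= q i / m. Adjusted p-values
#' are the usual backward cumulative minimum of m p(i) / i, capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return list with `reject` (logical, original order) and `p_adj`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (!length(pvals)) return(list(reject = logical(0), p_adj = numeric(0)))
  if (anyNA(pvals)) stop("p-values must not contain NA")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  thresh <- q * seq_len(m) / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  reject <- logical(m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(pmin(m * ps / seq_len(m), 1))))
  p_adj <- numeric(m)
  p_adj[o] <- adj
  list(reject = reject, p_adj = p_adj)
}
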