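# Over-representation analysis of a query gene list against gene-set
# collections: the exact upper-tail hypergeometric probability, computed in
# log space, with BH control across the retained sets.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts query genes falling in a set of size K, for a
#' query of size n drawn without replacement from a universe of size N:
#' the exact tail sum of C(K,i) C(N-K, n-i) / C(N,n) over i >= k,
#' accumulated in log space for numerical stability.
#'
#' @param k Observed overlap, 0 <= k <= min(K, n).
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) != round(c(k, K, n, N))) || any(c(k, K, n, N) < 0)) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N) stop("K and n must not exceed the universe size N")
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  lo <- max(0, n + K - N)
  if (k <= lo) return(1)
  i <- k:min(K, n)
  logs <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logs)
  min(exp(m + log(sum(exp(logs - m)))), 1)
}

#' Gene-set over-representation analysis
#'
#' Intersects the query and every gene set with the universe, drops sets
#' with empty intersection (with a message), computes the exact
#' hypergeometric upper tail per set, BH-adjusts across retained sets, and
#' sorts by q then p. The recommended universe is the genes passing the
#' candidate prevalence filter, not the whole annotation.
#'
#' @param query Character vector of query gene ids (e.g. linked DE genes).
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @param cfg A [pipeline_config()]; `q_max` is the significance threshold.
#' @return data.frame: set_name, k, K, n, N, p, q, significant.
#' @export
run_enrichment <- function(query, gene_sets, universe,
                           cfg = pipeline_config()) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (!length(query)) stop("query is empty after intersection with the universe")
  sets <- lapply(gene_sets, intersect, y = universe)
  keep <- lengths(sets) > 0
  if (any(!keep)) {
    message(sum(!keep), " gene set(s) dropped: no members in the universe")
  }
  sets <- sets[keep]
  if (!length(sets)) stop("no gene sets overlap the universe")
  N <- length(universe)
  n <- length(query)
  k <- vapply(sets, function(s) length(intersect(query, s)), 1L)
  K <- lengths(sets)
  p <- vapply(seq_along(sets), function(i) hypergeom_upper(k[i], K[i], n, N),
              numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(set_name = names(sets), k = k, K = K, n = n, N = N,
                    p = p, q = q, significant = q < cfg$q_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
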