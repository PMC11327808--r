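# Gene-set over-representation analysis (ORA): hypergeometric upper-tail
# tests of per-organ foreground gene lists against GMT collections.

#' Hypergeometric over-representation p-value
#'
#' Upper tail `P(X >= k)` for X hypergeometric: drawing `n` genes
#' (the foreground) from a universe of `N` of which `K` belong to the set,
#' how surprising is an overlap of `k` or more? Computed via
#' `stats::phyper`, which works on log scale internally, so tiny tails are
#' returned accurately.
#'
#' @param k Foreground genes in the set (0 <= k <= min(n, K)).
#' @param n Foreground size.
#' @param K Universe genes annotated to the set.
#' @param N Universe size.
#' @return The upper-tail p-value. Vectorised over its arguments.
#' @examples
#' hypergeom_pvalue(21, 283, 133, 5400)  # ~4.36e-06
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  bad <- k < 0 | n < 0 | K < 0 | N < 0 | k > n | k > K | n > N | K > N
  if (any(bad))
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests every set in a collection for enrichment of the foreground within
#' a background universe. By default the universe is restricted to
#' background genes annotated to at least one set of the collection (the
#' convention behind fixed per-collection denominators in ORA tables);
#' pass `restrict_to_annotated = FALSE` to use the full background.
#'
#' @param foreground Character vector of gene ids; must be a subset of
#'   `background`.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param background Character vector: the universe of genes eligible for
#'   selection (e.g. all genes passing the abundance filter).
#' @param restrict_to_annotated Restrict the universe to annotated genes
#'   (default `TRUE`).
#' @return A data.frame sorted by ascending p: `set_id`, `k`, `n`, `K`,
#'   `N`, `p_value`, `q_value` (BH over the collection's sets).
#' @export
enrich <- function(foreground, collection, background,
                   restrict_to_annotated = TRUE) {
  foreground <- unique(foreground)
  background <- unique(background)
  stray <- setdiff(foreground, background)
  if (length(stray))
    stop("foreground gene(s) absent from background: ",
         paste(stray, collapse = ", "))
  if (!length(collection)) stop("empty gene-set collection")
  if (restrict_to_annotated) {
    annotated <- unique(unlist(collection, use.names = FALSE))
    background <- intersect(background, annotated)
    foreground <- intersect(foreground, background)
  }
  N <- length(background)
  n <- length(foreground)
  K <- vapply(collection, function(s)
    length(intersect(s, background)), integer(1L))
  k <- vapply(collection, function(s)
    length(intersect(s, foreground)), integer(1L))
  p <- hypergeom_pvalue(k, n, K, N)
  res <- data.frame(set_id = names(collection), k = k, n = n, K = K, N = N,
                    p_value = p,
                    q_value = fdr_qvalues(p, "bh"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p_value, res$set_id), , drop = FALSE]
}
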