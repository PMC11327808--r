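# Organ-relatedness analysis: Bray-Curtis dissimilarity between organ
# expression profiles and agglomerative clustering of the organs.

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' `sum(|u - v|) / sum(u + v)`: 0 for identical profiles, 1 for profiles
#' with disjoint support. Defined for non-negative vectors that are not
#' both all zero.
#'
#' @param u,v Equal-length non-negative numeric vectors.
#' @return The dissimilarity, in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("profiles differ in length")
  if (any(u < 0) || any(v < 0)) stop("profiles must be non-negative")
  denom <- sum(u) + sum(v)
  if (denom == 0) stop("both profiles are all zero")
  sum(abs(u - v)) / denom
}

#' Pairwise Bray-Curtis distances between organ profiles
#'
#' Each organ's profile is its column of per-organ mean FPKMs over all
#' genes; distances are computed with [vegan::vegdist()].
#'
#' @param organ_means Genes x organs matrix from [organ_means()].
#' @return Symmetric organs x organs matrix with zero diagonal.
#' @export
distance_matrix <- function(organ_means) {
  if (ncol(organ_means) < 2L) stop("need >= 2 organs")
  if (any(organ_means < 0)) stop("negative abundances")
  d <- vegan::vegdist(t(organ_means), method = "bray")
  as.matrix(d)
}

#' Hierarchical clustering of organs
#'
#' Agglomerative clustering of a distance matrix; average linkage (UPGMA)
#' by default, the usual companion of Bray-Curtis. Returns a standard
#' `hclust` object whose merge heights are non-decreasing under average
#' and complete linkage.
#'
#' @param dist Symmetric distance matrix (or `dist` object).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` object with organ codes as labels.
#' @export
hcluster <- function(dist, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist)))
      stop("distance matrix is not symmetric")
    dist <- stats::as.dist(dist)
  }
  stats::hclust(dist, method = linkage)
}

#' Newick serialisation of a cluster tree
#'
#' Converts the `hclust` tree to a phylogeny ([ape::as.phylo()]) and writes
#' Newick; each leaf sits at depth half its merge height, so branch lengths
#' are half merge-height differences.
#'
#' @param tree An `hclust` object from [hcluster()].
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}
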