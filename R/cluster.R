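#' Average-linkage (UPGMA) clustering of treatments
#'
#' Agglomerative hierarchical clustering of treatment rows on a Euclidean
#' distance matrix with unweighted average linkage: the distance between
#' two clusters is the arithmetic mean of all pairwise inter-cluster
#' distances. Average linkage on a metric is monotone, so merge heights
#' are non-decreasing and a horizontal cut at any height yields a unique
#' grouping.
#'
#' @param x numeric matrix or data.frame of treatment rows (e.g. the four
#'   behavioural proportions per treatment); row names become leaf labels.
#' @param labels optional leaf labels overriding row names.
#' @return object of class `treatment_dendrogram`: list with `merges`
#'   (data.frame `a`, `b`, `height` in merge order, negative indices
#'   denoting leaves as in [stats::hclust()]), `labels`, and the
#'   underlying `hclust` object in `hclust`.
#' @export
cluster_treatments <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need >= 2 rows to cluster")
  if (!all(is.finite(x))) abort("`x` must be finite")
  labels <- labels %||% rownames(x) %||% paste0("t", seq_len(nrow(x)))
  if (length(labels) != nrow(x)) abort("one label per row required")
  rownames(x) <- labels
  hc <- hclust(dist(x, method = "euclidean"), method = "average")
  structure(
    list(merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                             height = hc$height),
         labels = labels, hclust = hc),
    class = "treatment_dendrogram")
}

#' Cut a dendrogram at a height
#'
#' @param dend a `treatment_dendrogram`.
#' @param height cut height; merges above it are undone.
#' @return named integer vector of group memberships (one per leaf).
#' @export
cut_dendrogram <- function(dend, height) {
  stopifnot(inherits(dend, "treatment_dendrogram"))
  cutree(dend$hclust, h = height)
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are derived from merge heights (ultrametric tree), so
#' the dendrogram round-trips through standard phylogenetic tools.
#'
#' @param dend a `treatment_dendrogram`.
#' @param file optional path; when given the Newick string is written
#'   there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
dendrogram_newick <- function(dend, file = NULL) {
  stopifnot(inherits(dend, "treatment_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' @export
print.treatment_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, %d merges\n",
              length(x$labels), nrow(x$merges)))
  print(x$merges, row.names = FALSE)
  invisible(x)
}
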