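# Hierarchical clustering of subjects on their methylation profiles.

#' Cluster subjects on methylation profiles
#'
#' Computes pairwise Euclidean distances between per-sample methylation
#' vectors over the CpGs of the set (sites with any missing value are dropped
#' from the distance computation) and builds an agglomerative dendrogram.
#'
#' @param x A [TrioMethExperiment-class] (at least 2 samples).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return List with `hclust` (the merge tree), `dist` (the distance matrix),
#'   `newick` (Newick string of the dendrogram, `NULL` for 2 samples) and
#'   `nCpGs` (sites used).
#' @export
clusterSubjects <- function(x, linkage = "complete") {
    stopifnot(is(x, "TrioMethExperiment"))
    if (ncol(x) < 2L) stop("need at least 2 samples")
    meth <- methAssay(x)
    keep <- complete.cases(meth)
    if (!any(keep))
        stop("no CpGs with complete data across samples")
    d <- dist(t(meth[keep, , drop = FALSE]), method = "euclidean")
    hc <- hclust(d, method = linkage)
    nwk <- if (ncol(x) >= 3L) ape::write.tree(ape::as.phylo(hc)) else NULL
    list(hclust = hc, dist = d, newick = nwk, nCpGs = sum(keep))
}
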