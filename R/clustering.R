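# Hierarchical clustering of specificity matrices into motif groups and
# Newick export of the resulting dendrogram.

#' Feature matrix for motif clustering
#'
#' Each kinase becomes one row: the concatenation over the 10 flanking
#' positions of its normalized values for the unmodified amino acids
#' excluding Tyr (which is fixed identical to Phe and therefore
#' redundant), plus the phosphothreonine and phosphotyrosine rows.
#'
#' @param pssms Named list of [pssm()] objects.
#' @return Numeric matrix, kinases (rows, sorted by id) x 210 features.
#' @export
motif_features <- function(pssms) {
  if (length(pssms) < 2L) stop("need at least 2 PSSMs to cluster")
  keep <- c(setdiff(AA_NATURAL, "Y"), AA_PTM)
  rows <- lapply(pssms, function(p) as.vector(p$values[keep, , drop = FALSE]))
  lens <- vapply(rows, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("dimension mismatch: PSSMs span different feature spaces")
  }
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(pssms, `[[`, "", "kinase_id")
  m[order(rownames(m)), , drop = FALSE]
}

#' Ward-linkage clustering of kinase motifs
#'
#' Hierarchically clusters motif feature vectors with Ward's minimum
#' variance criterion on Euclidean distances (`hclust` method
#' `"ward.D2"`, the Ward formulation defined on raw distances).  Input
#' order does not affect the tree: kinases are sorted by id before
#' clustering.
#'
#' @param pssms Named list of [pssm()] objects.
#' @return `hclust` object with kinase ids as labels.
#' @export
cluster_motifs <- function(pssms) {
  m <- motif_features(pssms)
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Convert a dendrogram to a Newick string
#'
#' Uses the ultrametric convention: leaves sit at depth 0 and each merge
#' at half its linkage height, so every child branch length is
#' (parent height - child height) / 2 and a pair merging at height h is
#' written `(A:h/2,B:h/2);`.
#'
#' @param hc `hclust` object (e.g. from [cluster_motifs()]).
#' @param path Optional file path; when given the tree is also written
#'   there.
#' @return Newick string (invisibly the path when `path` is given).
#' @export
to_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}

#' Flat specificity groups at a requested tree cut
#'
#' @param hc `hclust` object.
#' @param k Number of groups.
#' @return Data frame `kinase_id`, `cluster` (integer), sorted by id.
#' @export
cut_motif_clusters <- function(hc, k) {
  cl <- stats::cutree(hc, k = k)
  out <- data.frame(kinase_id = names(cl), cluster = as.integer(cl),
                    stringsAsFactors = FALSE)
  out <- out[order(out$kinase_id), ]
  rownames(out) <- NULL
  out
}
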