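# Consistency of selected-feature structure across trained models:
# a weighted domain-frequency similarity, and a Jaccard score over
# data-driven feature clusters (complete-linkage clustering of the
# absolute Spearman correlation matrix, distance cutoff 0.7).

#' Domain selection-frequency profile of a CV report
#' @param report a [nestedLoso()] result.
#' @return named numeric vector over the four EEG feature domains.
#' @export
domainFrequencies <- function(report) selectionFrequency(report)$domain

#' Weighted domain-consistency score between two models
#'
#' `1 - sum(w_d * |fA_d - fB_d|) / sum(w_d)`, where the domain weights
#' `w_d` are the mean selection frequency of each domain across all
#' compared datasets (by default, the two being compared). Bounded in
#' \[0, 1\]; identical profiles score 1.
#'
#' @param freqA,freqB domain-frequency vectors ([domainFrequencies()]).
#' @param weights domain weights; supply the mean profile over *all*
#'   datasets when scoring several pairs.
#' @return similarity score in \[0, 1\].
#' @export
domainConsistency <- function(freqA, freqB,
                              weights = (freqA + freqB) / 2) {
  stopifnot(length(freqA) == length(freqB),
            length(weights) == length(freqA))
  if (sum(weights) <= 0) stop("all-zero domain weights")
  1 - sum(weights * abs(freqA - freqB)) / sum(weights)
}

#' Data-driven feature clusters
#'
#' Hierarchical agglomerative clustering with complete linkage on the
#' distance `1 - |Spearman correlation|` between features, cut at
#' height 0.7 (so any two features merged into a cluster correlate
#' with `|rho| >= 0.3`). Constant features get `|rho| = 0` against
#' everything and end up in singleton clusters (with a warning).
#'
#' @param X epochs x features matrix (named columns), e.g.
#'   `t(assay(se))`.
#' @param cutoff tree-cut height on the correlation distance.
#' @return list with `assignment` (named integer vector feature ->
#'   cluster id), `n_clusters`, and the `hclust` tree.
#' @export
clusterFeatures <- function(X, cutoff = 0.7) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two features to cluster")
  if (anyNA(X)) stop("feature matrix contains missing values")
  flat <- apply(X, 2, sd) == 0
  if (any(flat))
    warning("constant feature(s) assigned singleton clusters: ",
            paste(colnames(X)[flat], collapse = ", "))
  rho <- suppressWarnings(cor(X, method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  d <- as.dist(1 - abs(rho))
  tree <- hclust(d, method = "complete")
  assignment <- cutree(tree, h = cutoff)
  list(assignment = assignment, n_clusters = max(assignment),
       tree = tree)
}

#' Cluster-consistency (Jaccard) score between two selected-feature sets
#'
#' Maps each dataset's selected features onto a reference clustering
#' and returns the Jaccard similarity of the two sets of touched
#' clusters. Invariant to *which* member of a cluster was selected.
#'
#' @param clusters a [clusterFeatures()] result (the reference
#'   clustering, computed on one dataset's feature matrix).
#' @param selectedA,selectedB character vectors of selected feature
#'   names (e.g. `unique(unlist(report$selected))`).
#' @return Jaccard similarity in \[0, 1\].
#' @export
clusterConsistency <- function(clusters, selectedA, selectedB) {
  if (!length(selectedA) && !length(selectedB))
    stop("both selected-feature sets are empty")
  toClusters <- function(sel) {
    idx <- clusters$assignment[intersect(sel, names(clusters$assignment))]
    unique(unname(idx))
  }
  a <- toClusters(selectedA); b <- toClusters(selectedB)
  length(intersect(a, b)) / length(union(a, b))
}
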