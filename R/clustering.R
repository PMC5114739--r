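#' Assemble the 28-feature immune infiltration panel
#'
#' Scores an expression cohort jointly (shared range normalization) with
#' the expanded immune panel: the 24 immune cell type signatures, the
#' 40-gene angiogenesis signature, and the three single-gene
#' immunotherapy-target signatures (PD-1, PD-L1, CTLA-4) - 28 features in
#' all, one row per feature, columns in input sample order.
#'
#' @param expr gene-by-sample expression matrix.
#' @param alpha rank-weight exponent (default 0.25).
#' @param minGenesPresent passed to [ssgseaScores()].
#' @return 28-by-samples numeric feature matrix.
#' @export
assembleFeaturePanel <- function(expr, alpha = 0.25, minGenesPresent = 1L) {
  panel <- SignatureCollection(
    c(builtinSignatures("bindea24")@signatures,
      builtinSignatures("angiogenesis")@signatures,
      builtinSignatures("checkpoint_targets")@signatures),
    source = "builtin:panel28")
  stopifnot(length(panel) == 28L)
  ssgseaScores(expr, panel, alpha = alpha, normalize = TRUE,
               minGenesPresent = minGenesPresent)
}

#' Hierarchical clustering of a feature panel
#'
#' Agglomerative clustering of samples with Ward linkage on Euclidean
#' distances over the feature columns (the classical Ward criterion via
#' the Lance-Williams update on squared Euclidean distances, i.e.
#' \code{hclust(method = "ward.D2")}), cut into \code{k} clusters.
#' Features enter as ssGSEA scores without per-feature re-standardization
#' by default; set \code{standardize = TRUE} to z-score feature rows first.
#' Deterministic for fixed input.
#'
#' @param panel feature-by-sample matrix, e.g. from
#'   [assembleFeaturePanel()].
#' @param k number of clusters (default 3; at most the number of samples).
#' @param standardize z-score the feature rows first? Default
#'   \code{FALSE}.
#' @return integer vector of cluster ids (1..k), named by sample.
#' @export
clusterCohort <- function(panel, k = 3L, standardize = FALSE) {
  stopifnot(is.matrix(panel), k >= 1L)
  if (ncol(panel) < k) stop("fewer samples than clusters")
  if (standardize) panel <- standardizeScores(panel)
  hc <- hclust(dist(t(panel), method = "euclidean"), method = "ward.D2")
  cutree(hc, k = k)
}

#' Semantic labels for three immune infiltration clusters
#'
#' Ranks the k = 3 clusters by the mean of the T cell subset feature rows:
#' the highest cluster is labelled \code{T_cell_enriched}, the lowest
#' \code{non_infiltrated}, and the middle one
#' \code{heterogeneously_infiltrated}. Exact ties are broken by the mean of
#' the checkpoint-target feature rows (deterministic); an all-equal panel
#' yields an arbitrary but deterministic labeling with a warning. The rule
#' is a declared package convention for naming discovered clusters.
#'
#' @param labels integer cluster ids from [clusterCohort()] with k = 3.
#' @param panel the feature matrix the clustering used.
#' @param tCellFeatures feature rows used for ranking; defaults to the
#'   nine TIS constituents.
#' @param tieBreakFeatures rows for tie-breaking; defaults to the three
#'   checkpoint targets.
#' @return data.frame with columns \code{sample}, \code{cluster} and
#'   \code{label} (factor with levels \code{T_cell_enriched},
#'   \code{heterogeneously_infiltrated}, \code{non_infiltrated}).
#' @export
labelClusters <- function(labels, panel,
                          tCellFeatures = tisDefinition()@constituents,
                          tieBreakFeatures = c("PD-1", "PD-L1", "CTLA-4")) {
  stopifnot(is.matrix(panel), length(labels) == ncol(panel))
  ids <- sort(unique(labels))
  if (length(ids) != 3L) {
    warning("semantic labeling requires exactly 3 clusters; returning ids")
    return(data.frame(sample = colnames(panel), cluster = labels,
                      label = NA_character_, stringsAsFactors = FALSE))
  }
  tRows <- intersect(tCellFeatures, rownames(panel))
  if (length(tRows) == 0L) stop("no T cell feature rows in panel")
  tMean <- vapply(ids, function(cl)
    mean(panel[tRows, labels == cl, drop = FALSE]), 0)
  if (anyDuplicated(tMean)) {
    bRows <- intersect(tieBreakFeatures, rownames(panel))
    bMean <- vapply(ids, function(cl)
      mean(panel[bRows, labels == cl, drop = FALSE]), 0)
    if (anyDuplicated(cbind(tMean, bMean)))
      warning("tied cluster means; labeling is arbitrary but deterministic")
    ord <- order(tMean, bMean, ids, decreasing = TRUE)
  } else ord <- order(tMean, decreasing = TRUE)
  lvls <- c("T_cell_enriched", "heterogeneously_infiltrated",
            "non_infiltrated")
  lab <- character(3L)
  lab[ord] <- lvls
  names(lab) <- as.character(ids)
  data.frame(sample = colnames(panel), cluster = labels,
             label = factor(lab[as.character(labels)], levels = lvls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Nearest-centroid assignment of new samples to discovered clusters
#'
#' Assigns each new feature column to the cluster with the nearest
#' (Euclidean) centroid of the training panel. This is a lightweight
#' convenience for transferring cluster structure to new cohorts; it is
#' not a trained classifier.
#'
#' @param panel training feature-by-sample matrix.
#' @param labels training cluster ids.
#' @param newPanel feature-by-sample matrix with the same feature rows.
#' @return integer cluster ids for the new samples.
#' @export
predictNearestCentroid <- function(panel, labels, newPanel) {
  stopifnot(is.matrix(panel), is.matrix(newPanel),
            identical(rownames(panel), rownames(newPanel)),
            length(labels) == ncol(panel))
  ids <- sort(unique(labels))
  centroids <- vapply(ids, function(cl)
    rowMeans(panel[, labels == cl, drop = FALSE]), numeric(nrow(panel)))
  d2 <- vapply(seq_along(ids), function(j)
    colSums((newPanel - centroids[, j])^2), numeric(ncol(newPanel)))
  ids[max.col(-matrix(d2, ncol(newPanel), length(ids)))]
}
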