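#' Standardize a score matrix across samples
#'
#' Each signature row is centered to mean 0 and scaled to standard
#' deviation 1 (sample sd, n-1 denominator) across all samples provided.
#' The standardization pool is exactly the sample set of the matrix;
#' cohorts to be compared on a common scale must be standardized jointly.
#'
#' @param scores signature-by-sample numeric matrix (at least 2 samples).
#' @return matrix of z-values with the same dimnames.
#' @examples
#' standardizeScores(matrix(1:3, 1, 3,
#'                          dimnames = list("A", paste0("s", 1:3))))
#' @export
standardizeScores <- function(scores) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (ncol(scores) < 2L) stop("standardization needs at least 2 samples")
  sds <- apply(scores, 1L, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop(sprintf("zero-variance signature row(s): %s",
                 paste(rownames(scores)[zero], collapse = ", ")))
  t(scale(t(scores)))[, , drop = FALSE]
}

#' T cell infiltration score (TIS) definition
#'
#' The TIS aggregates the standardized scores of nine T cell subsets:
#' CD8 T, T helper, T, T central memory, T effector memory, Th1, Th2, Th17
#' and Treg cells. The gamma-delta T cell and follicular helper T cell
#' signatures are documented exclusions (their signature genes are also
#' expressed in healthy brain tissue).
#'
#' @param reduction \code{"mean"} (default) or \code{"sum"}. The two differ
#'   by the constant factor 9 and are rank-identical.
#' @return an \linkS4class{AggregateDefinition} with 9 constituents.
#' @export
tisDefinition <- function(reduction = c("mean", "sum")) {
  AggregateDefinition("TIS",
    constituents = c("CD8 T cells", "T helper cells", "T cells", "Tcm",
                     "Tem", "Th1 cells", "Th2 cells", "Th17 cells", "Treg"),
    exclusions = c("Tgd", "Tfh"),
    reduction = match.arg(reduction))
}

#' Overall immune infiltration score (IIS) definition
#'
#' The IIS aggregates the standardized scores of macrophages, the four
#' dendritic cell subsets (total, plasmacytoid, immature, activated),
#' B cells, cytotoxic cells, eosinophils, mast cells, neutrophils, the
#' three NK subsets (total, CD56bright, CD56dim) and all nine T cell
#' subsets of the TIS. Gamma-delta and follicular helper T cells are
#' excluded, as for the TIS.
#'
#' @inheritParams tisDefinition
#' @return an \linkS4class{AggregateDefinition} with 22 constituents.
#' @export
iisDefinition <- function(reduction = c("mean", "sum")) {
  AggregateDefinition("IIS",
    constituents = c("Macrophages", "DC", "pDC", "iDC", "aDC", "B cells",
                     "Cytotoxic cells", "Eosinophils", "Mast cells",
                     "Neutrophils", "NK cells", "NK CD56bright cells",
                     "NK CD56dim cells",
                     "CD8 T cells", "T helper cells", "T cells", "Tcm",
                     "Tem", "Th1 cells", "Th2 cells", "Th17 cells", "Treg"),
    exclusions = c("Tgd", "Tfh"),
    reduction = match.arg(reduction))
}

#' Aggregate standardized scores into a per-sample index
#'
#' Reduces the constituent rows of a standardized score matrix to one value
#' per sample (arithmetic mean by default, or sum). Excluded signatures
#' never contribute, whether or not they are present in the matrix. The APM
#' score, by contrast, is not an aggregate: it is the ssGSEA score of the
#' seven-gene antigen presenting machinery signature used directly.
#'
#' @param z standardized signature-by-sample matrix (see
#'   [standardizeScores()]).
#' @param definition an \linkS4class{AggregateDefinition}.
#' @return named per-sample numeric vector.
#' @export
aggregateScore <- function(z, definition) {
  stopifnot(is.matrix(z), is(definition, "AggregateDefinition"))
  missing <- setdiff(definition@constituents, rownames(z))
  if (length(missing))
    stop(sprintf("aggregate '%s': missing constituent row(s): %s",
                 definition@name, paste(missing, collapse = ", ")))
  sub <- z[definition@constituents, , drop = FALSE]
  if (definition@reduction == "mean") colMeans(sub) else colSums(sub)
}

#' Log cell-count ratio from two score rows
#'
#' ssGSEA infiltration scores do not follow count distributions, so a ratio
#' of cell counts cannot be formed by division; but since
#' log(a/b) = log(a) - log(b), the difference of two scores represents the
#' log ratio of the two cell levels. Shipped preset pairs of interest are
#' CD8 T/Treg and Th17/Th2.
#'
#' @param scores signature-by-sample matrix (raw or standardized).
#' @param numerator,denominator signature row names.
#' @return named per-sample numeric vector of score differences,
#'   interpreted as log(numerator/denominator).
#' @export
logRatio <- function(scores, numerator, denominator) {
  stopifnot(is.matrix(scores))
  for (nm in c(numerator, denominator))
    if (!nm %in% rownames(scores))
      stop(sprintf("unknown signature '%s'", nm))
  scores[numerator, ] - scores[denominator, ]
}

#' Median split of a per-sample score
#'
#' Partitions samples into a low group (value <= median) and a high group
#' (value > median), the stratification used for ratio-based survival
#' grouping (survival modeling itself is outside this package).
#'
#' @param values named per-sample numeric vector, e.g. from [logRatio()].
#' @return factor with levels \code{"low"} and \code{"high"}.
#' @export
medianSplit <- function(values) {
  med <- stats::median(values)
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

#' Read aggregate definitions from a YAML or JSON config file
#'
#' The file holds a list of entries with fields \code{name},
#' \code{constituents}, and optionally \code{exclusions} and
#' \code{reduction} (\code{"mean"} default).
#'
#' @param path path to a YAML (or JSON, which YAML supersets) file.
#' @return named list of \linkS4class{AggregateDefinition} objects.
#' @export
readAggregateDefinitions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(x) {
    stopifnot(!is.null(x$name), !is.null(x$constituents))
    AggregateDefinition(x$name,
      constituents = unlist(x$constituents),
      exclusions = if (is.null(x$exclusions)) character()
                   else unlist(x$exclusions),
      reduction = if (is.null(x$reduction)) "mean" else x$reduction)
  })
  names(defs) <- vapply(defs, slot, "", "name")
  defs
}
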