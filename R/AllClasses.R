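#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor density rlnorm rnorm runif sd hclust dist cutree
#' @importFrom utils read.delim write.table
NULL

#' GeneSignature: a named list of marker genes
#'
#' A gene signature is a nonempty, duplicate-free, ordered set of gene
#' symbols (HGNC-style, matched by exact case-sensitive text equality)
#' together with a text label. Single-gene signatures are valid: in the
#' packaged immune collection the regulatory T cell signature is
#' \code{FOXP3} alone and the plasmacytoid dendritic cell signature is
#' \code{IL3RA} alone.
#'
#' @slot name single nonempty character label.
#' @slot genes character vector of gene symbols, nonempty, no duplicates.
#'
#' @examples
#' GeneSignature("Treg", "FOXP3")
#' @export
setClass("GeneSignature",
  representation(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("'name' must be a single nonempty string")
  if (length(object@genes) == 0L)
    return("'genes' must be nonempty")
  if (anyNA(object@genes) || !all(nzchar(object@genes)))
    return("'genes' must not contain NA or empty symbols")
  if (anyDuplicated(object@genes))
    return(sprintf("duplicate gene symbols in signature '%s': %s",
                   object@name,
                   paste(unique(object@genes[duplicated(object@genes)]),
                         collapse = ", ")))
  TRUE
})

#' @param name single character label.
#' @param genes character vector of gene symbols.
#' @rdname GeneSignature-class
#' @export
GeneSignature <- function(name, genes) {
  new("GeneSignature", name = as.character(name), genes = as.character(genes))
}

#' SignatureCollection: a set of gene signatures with unique names
#'
#' @slot signatures list of \linkS4class{GeneSignature} objects with unique
#'   names.
#' @slot source free-text provenance tag for the collection.
#'
#' @seealso [readGMT()], [builtinSignatures()], [signatureStats()]
#' @export
setClass("SignatureCollection",
  representation(signatures = "list", source = "character"))

setValidity("SignatureCollection", function(object) {
  if (!all(vapply(object@signatures, is, TRUE, "GeneSignature")))
    return("'signatures' must be a list of GeneSignature objects")
  nms <- vapply(object@signatures, slot, "", "name")
  if (anyDuplicated(nms))
    return(sprintf("duplicate signature names: %s",
                   paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (length(object@source) != 1L)
    return("'source' must be a single string")
  TRUE
})

#' @param signatures list of \linkS4class{GeneSignature} objects.
#' @param source provenance tag.
#' @rdname SignatureCollection-class
#' @export
SignatureCollection <- function(signatures = list(), source = "user") {
  sc <- new("SignatureCollection", signatures = signatures, source = source)
  names(sc@signatures) <- signatureNames(sc)
  sc
}

#' @describeIn SignatureCollection-class number of signatures.
#' @param x a SignatureCollection.
#' @export
setMethod("length", "SignatureCollection",
          function(x) length(x@signatures))

#' @describeIn SignatureCollection-class signature names.
#' @export
setMethod("names", "SignatureCollection",
          function(x) signatureNames(x))

#' Signature names of a collection
#' @param x a \linkS4class{SignatureCollection}.
#' @return character vector of signature names.
#' @export
signatureNames <- function(x) {
  stopifnot(is(x, "SignatureCollection"))
  vapply(x@signatures, slot, "", "name", USE.NAMES = FALSE)
}

#' Gene list of one signature in a collection
#' @param x a \linkS4class{SignatureCollection} or
#'   \linkS4class{GeneSignature}.
#' @param name signature name (ignored for a single GeneSignature).
#' @return character vector of gene symbols.
#' @export
signatureGenes <- function(x, name = NULL) {
  if (is(x, "GeneSignature")) return(x@genes)
  stopifnot(is(x, "SignatureCollection"))
  i <- match(name, signatureNames(x))
  if (is.na(i))
    stop(sprintf("unknown signature '%s'; available: %s", name,
                 paste(signatureNames(x), collapse = ", ")))
  x@signatures[[i]]@genes
}

#' @export
setMethod("[[", "SignatureCollection", function(x, i, ...) {
  if (is.character(i)) {
    j <- match(i, signatureNames(x))
    if (is.na(j)) stop(sprintf("unknown signature '%s'", i))
    i <- j
  }
  x@signatures[[i]]
})

#' @param i signature names or indices to keep.
#' @rdname SignatureCollection-class
#' @export
setMethod("[", "SignatureCollection", function(x, i, ...) {
  if (is.character(i)) {
    j <- match(i, signatureNames(x))
    if (anyNA(j))
      stop(sprintf("unknown signature(s): %s",
                   paste(i[is.na(j)], collapse = ", ")))
    i <- j
  }
  SignatureCollection(x@signatures[i], source = x@source)
})

#' @export
setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (%d genes)\n", object@name,
              length(object@genes)))
  g <- object@genes
  if (length(g) > 8L) g <- c(g[1:8], "...")
  cat("  ", paste(g, collapse = ", "), "\n", sep = "")
})

#' @export
setMethod("show", "SignatureCollection", function(object) {
  cat(sprintf("SignatureCollection of %d signature(s) [source: %s]\n",
              length(object), object@source))
  sz <- vapply(object@signatures, function(s) length(s@genes), 0L)
  nm <- signatureNames(object)
  n <- min(length(nm), 10L)
  for (i in seq_len(n))
    cat(sprintf("  %-24s %d genes\n", nm[i], sz[i]))
  if (length(nm) > n) cat(sprintf("  ... and %d more\n", length(nm) - n))
})

#' AggregateDefinition: constituents of an aggregate infiltration index
#'
#' Defines an aggregate score (such as TIS or IIS) as the mean (or sum) of
#' standardized per-signature scores over a constituent list. Signatures
#' documented as excluded are carried for provenance and must never overlap
#' the constituents.
#'
#' @slot name aggregate label, e.g. \code{"TIS"}.
#' @slot constituents signature names entering the aggregate.
#' @slot exclusions signature names documented as excluded.
#' @slot reduction \code{"mean"} or \code{"sum"}.
#' @seealso [tisDefinition()], [iisDefinition()], [aggregateScore()]
#' @export
setClass("AggregateDefinition",
  representation(name = "character", constituents = "character",
                 exclusions = "character", reduction = "character"))

setValidity("AggregateDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single nonempty string")
  if (length(object@constituents) == 0L)
    return("'constituents' must be nonempty")
  if (anyDuplicated(object@constituents))
    return("duplicate constituents")
  bad <- intersect(object@constituents, object@exclusions)
  if (length(bad))
    return(sprintf("constituents also listed as exclusions: %s",
                   paste(bad, collapse = ", ")))
  if (!object@reduction %in% c("mean", "sum"))
    return("'reduction' must be \"mean\" or \"sum\"")
  TRUE
})

#' @param name aggregate label.
#' @param constituents character vector of signature names.
#' @param exclusions character vector of excluded signature names.
#' @param reduction \code{"mean"} (default) or \code{"sum"}.
#' @rdname AggregateDefinition-class
#' @export
AggregateDefinition <- function(name, constituents, exclusions = character(),
                                reduction = c("mean", "sum")) {
  new("AggregateDefinition", name = name,
      constituents = as.character(constituents),
      exclusions = as.character(exclusions),
      reduction = match.arg(reduction))
}

#' @export
setMethod("show", "AggregateDefinition", function(object) {
  cat(sprintf("AggregateDefinition '%s' (%s of %d constituents)\n",
              object@name, object@reduction, length(object@constituents)))
  cat("  constituents:", paste(object@constituents, collapse = ", "), "\n")
  if (length(object@exclusions))
    cat("  excluded:    ", paste(object@exclusions, collapse = ", "), "\n")
})

#' MixtureExperiment: in silico cell mixtures with known proportions
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay
#' \code{"mixture"} holds the gene-by-sample expression of simulated bulk
#' samples obtained as linear combinations of reference cell profiles; the
#' true mixing proportions live in \code{colData} (one column per cell
#' type), and the signal-to-noise ratio used for noise injection is kept in
#' \code{metadata(x)$snr} (\code{NA} for the noiseless mixture).
#'
#' @seealso [mixAndAddNoise()], [recoveryCorrelations()]
#' @export
setClass("MixtureExperiment", contains = "SummarizedExperiment")

setValidity("MixtureExperiment", function(object) {
  if (!"mixture" %in% SummarizedExperiment::assayNames(object))
    return("assay 'mixture' missing")
  p <- trueProportions(object)
  if (ncol(p) < 2L) return("needs at least two mixed cell types")
  if (any(abs(rowSums(p) - 1) > 1e-8))
    return("true mixing proportions must sum to 1 per sample")
  TRUE
})

#' True mixing proportions of a MixtureExperiment
#' @param x a \linkS4class{MixtureExperiment}.
#' @return samples-by-cell-type matrix of mixing weights (rows sum to 1).
#' @export
trueProportions <- function(x) {
  stopifnot(is(x, "MixtureExperiment"))
  as.matrix(SummarizedExperiment::colData(x))
}

#' Signal-to-noise ratio of a MixtureExperiment
#' @param x a \linkS4class{MixtureExperiment}.
#' @return scalar S of the S:1 noise level, or \code{NA} for the clean
#'   mixture.
#' @export
snrLevel <- function(x) {
  stopifnot(is(x, "MixtureExperiment"))
  S4Vectors::metadata(x)$snr
}

#' LeukocyteSignature: extreme-probe methylation signature
#'
#' Probes ranked by (mean leukocyte beta - mean tumor beta): the top
#' \code{nTop} probes form the leukocyte-hypermethylated set L_h and the
#' bottom \code{nTop} the leukocyte-hypomethylated set L_l. Per retained
#' probe, \code{leukocyteBeta} (B_k) is the mean beta over leukocyte
#' reference samples and \code{tumorAnchorBeta} (T_k) is the beta of the
#' theoretically purest tumor: the minimum observed tumor beta for L_h
#' probes and the maximum for L_l probes.
#'
#' @slot probesHigh probe ids in L_h.
#' @slot probesLow probe ids in L_l.
#' @slot leukocyteBeta named per-probe leukocyte reference beta B_k.
#' @slot tumorAnchorBeta named per-probe purest-tumor anchor beta T_k.
#' @seealso [buildLeukocyteSignature()], [probeFractions()]
#' @export
setClass("LeukocyteSignature",
  representation(probesHigh = "character", probesLow = "character",
                 leukocyteBeta = "numeric", tumorAnchorBeta = "numeric"))

setValidity("LeukocyteSignature", function(object) {
  if (length(intersect(object@probesHigh, object@probesLow)))
    return("L_h and L_l must be disjoint")
  probes <- c(object@probesHigh, object@probesLow)
  if (!all(probes %in% names(object@leukocyteBeta)) ||
      !all(probes %in% names(object@tumorAnchorBeta)))
    return("B_k and T_k must cover all signature probes")
  if (any(object@leukocyteBeta[probes] == object@tumorAnchorBeta[probes]))
    return("probes with B_k == T_k must be dropped")
  TRUE
})

#' @export
setMethod("show", "LeukocyteSignature", function(object) {
  cat(sprintf(paste0("LeukocyteSignature: %d leukocyte-high (L_h) and %d ",
                     "leukocyte-low (L_l) probes\n"),
              length(object@probesHigh), length(object@probesLow)))
})

#' SyntheticBetaCohort: simulated methylation cohort with known fractions
#'
#' @slot tumorBetas probe-by-sample matrix of tumor beta values in [0,1].
#' @slot referenceBetas probe-by-sample matrix of leukocyte reference betas.
#' @slot trueFractions per-tumor-sample true leukocyte fraction in [0,1].
#' @seealso [makeMethylationCohort()], [estimateLeukocyteFractions()]
#' @export
setClass("SyntheticBetaCohort",
  representation(tumorBetas = "matrix", referenceBetas = "matrix",
                 trueFractions = "numeric"))

setValidity("SyntheticBetaCohort", function(object) {
  if (min(object@tumorBetas) < 0 || max(object@tumorBetas) > 1 ||
      min(object@referenceBetas) < 0 || max(object@referenceBetas) > 1)
    return("beta values must lie in [0,1]")
  if (!identical(rownames(object@tumorBetas),
                 rownames(object@referenceBetas)))
    return("tumor and reference matrices must share the probe universe")
  if (length(object@trueFractions) != ncol(object@tumorBetas))
    return("one true fraction per tumor sample required")
  if (any(object@trueFractions < 0 | object@trueFractions > 1))
    return("true fractions must lie in [0,1]")
  TRUE
})

#' @export
setMethod("show", "SyntheticBetaCohort", function(object) {
  cat(sprintf(paste0("SyntheticBetaCohort: %d probes, %d tumor samples, ",
                     "%d leukocyte reference samples\n"),
              nrow(object@tumorBetas), ncol(object@tumorBetas),
              ncol(object@referenceBetas)))
  cat("  true leukocyte fractions:",
      paste(sprintf("%.2f", object@trueFractions), collapse = ", "), "\n")
})
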