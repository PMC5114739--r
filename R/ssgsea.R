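#' Per-sample rank transform of an expression matrix
#'
#' Within each sample (column), genes receive ascending ranks 1..p by
#' expression, so the most highly expressed gene gets rank p. Ties receive
#' the average rank. Because downstream enrichment scores use only these
#' ranks, they are invariant under any strictly increasing per-sample
#' transform of the expression values; negative values are accepted.
#'
#' @param expr numeric gene-by-sample matrix with unique rownames (gene
#'   symbols) and unique colnames (sample ids); no missing values.
#' @return matrix of the same shape holding per-column ranks.
#' @examples
#' m <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
#'             dimnames = list(paste0("g", 1:5), "s1"))
#' rankTransform(m)[, 1]
#' @export
rankTransform <- function(expr) {
  expr <- .checkExpr(expr)
  apply(expr, 2L, rank, ties.method = "average")
}

.checkExpr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix")
  if (nrow(expr) < 2L) stop("'expr' needs at least 2 genes")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("'expr' needs unique rownames (gene symbols)")
  if (is.null(colnames(expr))) colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  if (anyDuplicated(colnames(expr))) stop("'expr' needs unique sample ids")
  if (anyNA(expr)) stop("'expr' must not contain missing values")
  expr
}

# Precompute, per sample, everything signature-independent:
#  - walk position of every gene in the decreasing-rank order (ties, which
#    carry equal average ranks, are ordered among themselves by gene-id
#    lexicographic order so the walk is deterministic)
#  - the rank weight |rank|^alpha of every gene
# With these, the running-sum enrichment score of a signature with m genes
# at walk positions s_j and weights w_j has the closed form
#   ES = sum_j w_j (p - s_j + 1) / sum_j w_j
#        - [p(p+1)/2 - sum_j (p - s_j + 1)] / (p - m),
# the two terms being the summed in-set weighted ECDF and summed out-of-set
# ECDF of the walk. Evaluation is O(m) per sample and signature.
.ssgseaIndex <- function(expr, alpha = 0.25) {
  expr <- .checkExpr(expr)
  p <- nrow(expr)
  n <- ncol(expr)
  lex <- rank(rownames(expr), ties.method = "first") # lexicographic tie-break
  pos <- matrix(0L, p, n)
  wts <- matrix(0, p, n)
  for (j in seq_len(n)) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(-r, lex)
    pos[ord, j] <- seq_len(p)
    wts[, j] <- abs(r)^alpha
  }
  rownames(pos) <- rownames(wts) <- rownames(expr)
  list(pos = pos, wts = wts, p = p, n = n,
       samples = colnames(expr), genes = rownames(expr), alpha = alpha)
}

# ES for one signature (row indices into the gene universe), all samples.
.esFromIndex <- function(index, rows) {
  p <- index$p
  m <- length(rows)
  s <- index$pos[rows, , drop = FALSE]
  w <- index$wts[rows, , drop = FALSE]
  tailLen <- p - s + 1
  colSums(w * tailLen) / colSums(w) -
    (p * (p + 1) / 2 - colSums(tailLen)) / (p - m)
}

#' Running-sum enrichment score of one gene set in one sample
#'
#' Walks all genes of the sample in decreasing-rank order and accumulates
#' the difference between the rank-weighted in-set ECDF (weights
#' \eqn{|rank|^\alpha}) and the unweighted out-of-set ECDF; the enrichment
#' score is the sum of this difference over all walk steps. Genes of the
#' set absent from the matrix are dropped with a warning.
#'
#' @param rankColumn named numeric vector of per-gene ranks for one sample
#'   (as produced by [rankTransform()]).
#' @param geneSet a \linkS4class{GeneSignature} or character vector of gene
#'   symbols.
#' @param alpha nonnegative rank-weight exponent (default 0.25). At
#'   \code{alpha = 0} the in-set ECDF is unweighted.
#' @return a single enrichment score.
#' @examples
#' r <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
#' enrichmentScore(r, c("g1", "g2"))  # ~2.5139
#' @export
enrichmentScore <- function(rankColumn, geneSet, alpha = 0.25) {
  if (is(geneSet, "GeneSignature")) geneSet <- geneSet@genes
  stopifnot(is.numeric(rankColumn), !is.null(names(rankColumn)),
            alpha >= 0)
  p <- length(rankColumn)
  present <- geneSet %in% names(rankColumn)
  if (!all(present)) {
    warning(sprintf("%d signature gene(s) absent from the matrix: %s",
                    sum(!present),
                    paste(geneSet[!present], collapse = ", ")))
    geneSet <- geneSet[present]
  }
  m <- length(geneSet)
  if (m == 0L) stop("signature has no genes in matrix")
  if (m >= p)
    stop("signature covers the whole gene universe; out-of-set ECDF undefined")
  lex <- rank(names(rankColumn), ties.method = "first")
  ord <- order(-rankColumn, lex)
  pos <- integer(p); pos[ord] <- seq_len(p)
  idx <- match(geneSet, names(rankColumn))
  s <- pos[idx]
  w <- abs(rankColumn[idx])^alpha
  tailLen <- p - s + 1
  unname(sum(w * tailLen) / sum(w) - (p * (p + 1) / 2 - sum(tailLen)) / (p - m))
}

#' ssGSEA score matrix for a signature collection
#'
#' Computes the per-sample enrichment score of every signature in the
#' collection. When \code{normalize = TRUE} (the default, matching the
#' typical execution of this scoring method) every entry is divided by the
#' range (max - min) of the whole score matrix, taken jointly over all
#' signatures and samples; cohorts that must be comparable should therefore
#' be scored in one call.
#'
#' @param expr numeric gene-by-sample matrix (see [rankTransform()]).
#' @param collection a \linkS4class{SignatureCollection} (or single
#'   \linkS4class{GeneSignature}).
#' @param alpha nonnegative rank-weight exponent, default 0.25.
#' @param normalize divide by the global score range? Default \code{TRUE}.
#' @param minGenesPresent minimum number of signature genes that must be
#'   present in the matrix (default 1); fewer is an error naming the
#'   signature.
#' @return signature-by-sample numeric score matrix.
#' @examples
#' set.seed(1)
#' m <- matrix(rlnorm(600), 100, 6,
#'             dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
#' sigs <- SignatureCollection(list(GeneSignature("A", c("g001", "g002")),
#'                                  GeneSignature("B", c("g010", "g011"))))
#' ssgseaScores(m, sigs)
#' @export
ssgseaScores <- function(expr, collection, alpha = 0.25, normalize = TRUE,
                         minGenesPresent = 1L) {
  if (is(collection, "GeneSignature"))
    collection <- SignatureCollection(list(collection))
  stopifnot(is(collection, "SignatureCollection"), alpha >= 0,
            minGenesPresent >= 1L)
  if (length(collection) == 0L) stop("empty signature collection")
  index <- .ssgseaIndex(expr, alpha = alpha)
  nms <- signatureNames(collection)
  es <- matrix(NA_real_, length(collection), index$n,
               dimnames = list(nms, index$samples))
  for (i in seq_along(nms)) {
    genes <- collection@signatures[[i]]@genes
    rows <- match(genes, index$genes)
    absent <- is.na(rows)
    if (any(absent)) {
      if (sum(!absent) < minGenesPresent)
        stop(sprintf(
          "signature '%s': only %d of %d genes present (min %d required)",
          nms[i], sum(!absent), length(genes), minGenesPresent))
      warning(sprintf("signature '%s': dropping %d absent gene(s)",
                      nms[i], sum(absent)))
      rows <- rows[!absent]
    }
    if (length(rows) == 0L)
      stop(sprintf("signature '%s' has no genes in matrix", nms[i]))
    if (length(rows) >= index$p)
      stop(sprintf("signature '%s' covers the whole gene universe", nms[i]))
    es[i, ] <- .esFromIndex(index, rows)
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
    else warning("all scores identical; skipping range normalization")
  }
  es
}
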