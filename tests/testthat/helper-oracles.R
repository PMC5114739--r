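# Independent brute-force oracle for the running-sum enrichment score:
# literal walk over all genes in decreasing-rank order, accumulating the
# weighted in-set ECDF minus the unweighted out-of-set ECDF at every step.
# Deliberately naive (O(p) loop) and separate from the package's closed-form
# evaluation.
bruteEnrichmentScore <- function(expr_column, gene_ids, gene_set, alpha) {
  r <- rank(expr_column, ties.method = "average")
  lex <- rank(gene_ids, ties.method = "first")
  walk <- gene_ids[order(-r, lex)]
  inSet <- walk %in% gene_set
  w <- unname(abs(r[match(walk, gene_ids)])^alpha)
  p <- length(walk)
  m <- sum(inSet)
  stopifnot(m >= 1, m < p)
  totalIn <- sum(w[inSet])
  es <- 0
  cumIn <- 0
  cumOut <- 0
  for (i in seq_len(p)) {
    if (inSet[i]) cumIn <- cumIn + w[i] else cumOut <- cumOut + 1
    es <- es + cumIn / totalIn - cumOut / (p - m)
  }
  es
}

# small expression matrix with seeded values and canonical dimnames
randomExpr <- function(p, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rlnorm(p * n), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%02d", seq_len(n))))
}

writeTempGMT <- function(lines) {
  tf <- tempfile(fileext = ".gmt")
  writeLines(lines, tf)
  tf
}

# KDE-argmax oracle on the same fixed grid the estimator uses
kdeModeOracle <- function(x) {
  d <- stats::density(x, bw = stats::bw.nrd0(x), from = 0, to = 1, n = 1001)
  d$x[which.max(d$y)]
}

adjustedRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)
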