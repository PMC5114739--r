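#' Read a gene-by-sample expression (or beta) matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene (or
#' probe) identifiers; the delimiter is inferred from the file extension
#' (\code{.csv} = comma, otherwise tab). Duplicate identifiers and missing
#' values are errors: collapsing duplicate probes and imputing are
#' upstream preprocessing concerns.
#'
#' @param path input file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene/probe identifiers in first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  if (anyNA(m)) stop("missing values; drop or impute upstream")
  rownames(m) <- ids
  m
}

#' Write a signature-by-sample score matrix as TSV
#'
#' @param scores numeric matrix, e.g. from [ssgseaScores()].
#' @param path output file.
#' @param idColumn name of the first (identifier) column.
#' @return the path, invisibly.
#' @export
writeScoreMatrix <- function(scores, path, idColumn = "signature") {
  stopifnot(is.matrix(scores))
  df <- data.frame(rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
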