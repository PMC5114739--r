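#' Build the extreme-probe leukocyte methylation signature
#'
#' Ranks the shared probes by the difference between mean beta in the
#' leukocyte reference samples and mean beta in the tumor samples. The top
#' \code{nTop} probes (leukocyte-hypermethylated) form L_h, the bottom
#' \code{nTop} (leukocyte-hypomethylated) form L_l. Per probe, the
#' leukocyte representative value B_k is the mean over the reference
#' samples, and the purest-tumor anchor T_k is the minimum observed tumor
#' beta for L_h probes and the maximum for L_l probes. Probes with
#' B_k equal to T_k carry no information for the fraction formula and are
#' dropped with a warning.
#'
#' @param tumorBetas probe-by-sample beta matrix of tumor samples.
#' @param leukocyteRefBetas probe-by-sample beta matrix of leukocyte
#'   reference samples.
#' @param nTop probes per extreme set (default 1000).
#' @return a \linkS4class{LeukocyteSignature}.
#' @export
buildLeukocyteSignature <- function(tumorBetas, leukocyteRefBetas,
                                    nTop = 1000L) {
  stopifnot(is.matrix(tumorBetas), is.matrix(leukocyteRefBetas),
            nTop >= 1L, ncol(tumorBetas) >= 1L,
            ncol(leukocyteRefBetas) >= 1L)
  shared <- intersect(rownames(tumorBetas), rownames(leukocyteRefBetas))
  if (length(shared) < 2L * nTop)
    stop(sprintf(
      "need >= %d shared probes for top+bottom %d, got %d",
      2L * nTop, nTop, length(shared)))
  tum <- tumorBetas[shared, , drop = FALSE]
  ref <- leukocyteRefBetas[shared, , drop = FALSE]
  diff <- rowMeans(ref) - rowMeans(tum)
  ord <- order(diff, decreasing = TRUE)
  Lh <- shared[ord[seq_len(nTop)]]
  Ll <- shared[rev(ord)[seq_len(nTop)]]
  B <- rowMeans(ref)[c(Lh, Ll)]
  Tk <- c(apply(tum[Lh, , drop = FALSE], 1L, min),
          apply(tum[Ll, , drop = FALSE], 1L, max))
  names(Tk) <- c(Lh, Ll)
  degenerate <- names(Tk)[B[names(Tk)] == Tk]
  if (length(degenerate)) {
    warning(sprintf("dropping %d probe(s) with B_k == T_k",
                    length(degenerate)))
    Lh <- setdiff(Lh, degenerate)
    Ll <- setdiff(Ll, degenerate)
    keep <- c(Lh, Ll)
    B <- B[keep]
    Tk <- Tk[keep]
  }
  new("LeukocyteSignature", probesHigh = Lh, probesLow = Ll,
      leukocyteBeta = B, tumorAnchorBeta = Tk)
}

#' Per-probe leukocyte fractions for one tumor sample
#'
#' Inverts the two-component mixing model
#' T_ik = B_k f_ik + T_k (1 - f_ik), giving
#' f_ik = (T_ik - T_k) / (B_k - T_k) for every retained signature probe.
#' Values outside [0,1] are retained, not clipped: they inform the density
#' whose mode becomes the sample-level fraction, and their share is a
#' useful diagnostic.
#'
#' @param signature a \linkS4class{LeukocyteSignature}.
#' @param tumorColumn named per-probe beta vector for one tumor sample;
#'   must cover all retained signature probes.
#' @return named numeric vector of per-probe fractions f_ik (pooled over
#'   L_h and L_l).
#' @export
probeFractions <- function(signature, tumorColumn) {
  stopifnot(is(signature, "LeukocyteSignature"), is.numeric(tumorColumn),
            !is.null(names(tumorColumn)))
  probes <- c(signature@probesHigh, signature@probesLow)
  missing <- setdiff(probes, names(tumorColumn))
  if (length(missing))
    stop(sprintf("tumor column missing %d signature probe(s), e.g. %s",
                 length(missing), missing[1]))
  Tik <- tumorColumn[probes]
  B <- signature@leukocyteBeta[probes]
  Tk <- signature@tumorAnchorBeta[probes]
  (Tik - Tk) / (B - Tk)
}

#' Sample-level leukocyte fraction as the density mode of probe fractions
#'
#' Estimates a Gaussian kernel density (Silverman's rule-of-thumb
#' bandwidth) over the pooled per-probe fractions and returns the argmax of
#' the density evaluated on the fixed grid 0, 0.001, ..., 1. The mode
#' search is restricted to [0,1] because the leukocyte fraction is a
#' physical proportion; out-of-range f_ik values still shape the density.
#' A zero-variance f_ik vector short-circuits to the common value.
#'
#' @param fik numeric vector of per-probe fractions from
#'   [probeFractions()].
#' @param minProbes minimum number of finite values required (default 50).
#' @return the estimated leukocyte fraction f_i.
#' @export
leukocyteFraction <- function(fik, minProbes = 50L) {
  fik <- fik[is.finite(fik)]
  if (length(fik) < minProbes)
    stop(sprintf("too few finite probe fractions (%d < %d)",
                 length(fik), minProbes))
  if (sd(fik) == 0) return(unname(fik[1]))
  grid <- seq(0, 1, by = 0.001)
  dens <- density(fik, bw = stats::bw.nrd0(fik), from = 0, to = 1,
                  n = length(grid))
  grid[which.max(dens$y)]
}

#' Estimate leukocyte fractions for a tumor beta matrix
#'
#' Convenience wrapper: applies [probeFractions()] and
#' [leukocyteFraction()] to every tumor sample.
#'
#' @param signature a \linkS4class{LeukocyteSignature}.
#' @param tumorBetas probe-by-sample beta matrix.
#' @param minProbes passed to [leukocyteFraction()].
#' @return data.frame with columns \code{sample}, \code{fraction},
#'   \code{nProbesUsed} and \code{shareOutOfRange} (share of finite f_ik
#'   outside [0,1]).
#' @export
estimateLeukocyteFractions <- function(signature, tumorBetas,
                                       minProbes = 50L) {
  stopifnot(is.matrix(tumorBetas))
  res <- lapply(colnames(tumorBetas), function(s) {
    fik <- probeFractions(signature, tumorBetas[, s])
    fin <- fik[is.finite(fik)]
    data.frame(sample = s,
               fraction = leukocyteFraction(fik, minProbes = minProbes),
               nProbesUsed = length(fin),
               shareOutOfRange = mean(fin < 0 | fin > 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
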