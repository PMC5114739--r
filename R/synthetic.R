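#' Simulate mixing proportions by uniform spacings
#'
#' Generates, per sample, k random proportions that each follow the
#' Uniform(0,1) marginal and sum exactly to 1: draw k-1 U(0,1) numbers,
#' sort them ascending, and return the k spacings they induce on [0,1]
#' (the smallest draw, the consecutive differences, and one minus the
#' largest draw). The resulting vector is a Dirichlet(1,...,1) sample, so
#' each coordinate has marginal Beta(1, k-1) and mean 1/k.
#'
#' @param nSamples number of proportion vectors to draw.
#' @param k number of components (default 5; at least 2).
#' @param seed optional integer seed for reproducibility.
#' @return \code{nSamples} x \code{k} matrix; rows sum to 1, entries in
#'   (0,1).
#' @examples
#' p <- simulateMixingProportions(10, seed = 1)
#' rowSums(p)
#' @export
simulateMixingProportions <- function(nSamples, k = 5L, seed = NULL) {
  stopifnot(nSamples >= 1L, k >= 2L)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(runif(nSamples * (k - 1L)), nSamples, k - 1L)
  t(apply(u, 1L, .spacings))
}

# k spacings of k-1 uniforms: deterministic transform kept separate so the
# mapping from stated draws to proportions is directly testable
.spacings <- function(u) {
  s <- sort(u)
  c(s[1], diff(s), 1 - s[length(s)])
}

#' Synthetic reference expression profiles for cell types
#'
#' Builds one mean expression vector per cell type over a shared gene
#' universe: a common log-normal baseline is drawn per gene, and each
#' immune cell type overexpresses its own signature genes by a constant
#' fold factor. One additional non-immune profile (default label
#' \code{CD45neg}) overexpresses no signature genes, playing the role of
#' the tumor/stromal component of a mixture. The generator stands in for
#' sorted-population RNA-Seq profiles.
#'
#' @param collection a \linkS4class{SignatureCollection} holding the mapped
#'   signatures.
#' @param cellMap named character vector: names are cell type labels,
#'   values are signature names in \code{collection}. The mapped signatures
#'   must be pairwise disjoint in genes.
#' @param p total number of genes in the universe (default 20032).
#' @param fold overexpression factor for a cell type's own signature genes
#'   (default 5, > 1 for signal; \code{fold = 1} gives the no-signal null).
#' @param meanlog,sdlog parameters of the log-normal baseline (defaults 3
#'   and 1, mimicking normalized RNA-Seq scale).
#' @param nonImmuneLabel label of the signature-free profile.
#' @param seed optional integer seed.
#' @return list with elements \code{profiles} (p x (k+1) matrix, one
#'   column per cell type), \code{cellMap}, and \code{fold}.
#' @export
makeReferenceProfiles <- function(collection, cellMap = defaultCellMap(),
                                  p = 20032L, fold = 5, meanlog = 3,
                                  sdlog = 1, nonImmuneLabel = "CD45neg",
                                  seed = NULL) {
  stopifnot(is(collection, "SignatureCollection"), fold >= 1,
            length(cellMap) >= 1L, !is.null(names(cellMap)))
  if (!is.null(seed)) set.seed(seed)
  sigGenes <- lapply(cellMap, function(nm) signatureGenes(collection, nm))
  allSig <- unlist(sigGenes, use.names = FALSE)
  if (anyDuplicated(allSig))
    stop(sprintf("mapped signatures share gene(s): %s",
                 paste(unique(allSig[duplicated(allSig)]), collapse = ", ")))
  if (p < length(allSig))
    stop("'p' must be at least the number of mapped signature genes")
  filler <- sprintf("filler%05d", seq_len(p - length(allSig)))
  genes <- c(allSig, filler)
  baseline <- rlnorm(p, meanlog = meanlog, sdlog = sdlog)
  types <- c(names(cellMap), nonImmuneLabel)
  profiles <- matrix(rep(baseline, length(types)), p, length(types),
                     dimnames = list(genes, types))
  for (ct in names(cellMap)) {
    idx <- match(sigGenes[[ct]], genes)
    profiles[idx, ct] <- profiles[idx, ct] * fold
  }
  list(profiles = profiles, cellMap = cellMap, fold = fold)
}

#' Default cell-type-to-signature assignment for mixture experiments
#'
#' The four immune populations of the mixture benchmark, mapped to the
#' corresponding signatures of the packaged 24-signature collection:
#' macrophages, NK cells (scored with the CD56dim-equivalent total NK
#' signature), CD8 T cells, and CD4 T cells (scored with the umbrella
#' T helper signature, the collection having no CD4-specific list).
#'
#' @return named character vector mapping cell type labels to signature
#'   names.
#' @export
defaultCellMap <- function() {
  c(macrophage = "Macrophages", NK = "NK cells", CD8_T = "CD8 T cells",
    CD4_T = "T helper cells")
}

#' Mix reference profiles and inject signal-scaled Gaussian noise
#'
#' Forms, for each sample, the linear combination of the reference profiles
#' weighted by its true mixing proportions, then (optionally) adds
#' independent Gaussian noise per gene and sample with mean 0 and standard
#' deviation equal to the clean value divided by S for an S:1
#' signal-to-noise ratio. Noisy values are not clipped at zero: downstream
#' scoring is rank-based and negative readouts are legitimate noise
#' outcomes.
#'
#' @param refs reference profile list from [makeReferenceProfiles()].
#' @param proportions samples-by-cell-type matrix with unit row sums;
#'   columns must align with the columns of \code{refs$profiles} (matched
#'   by name when named).
#' @param snr positive scalar S of the S:1 noise level, or \code{NA}/
#'   \code{NULL} for the clean (noiseless) mixture.
#' @param seed optional integer seed.
#' @return a \linkS4class{MixtureExperiment}.
#' @export
mixAndAddNoise <- function(refs, proportions, snr = NA, seed = NULL) {
  stopifnot(is.list(refs), is.matrix(refs$profiles),
            is.matrix(proportions))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(snr)) snr <- NA_real_
  stopifnot(length(snr) == 1L, is.na(snr) || snr > 0)
  prof <- refs$profiles
  if (ncol(proportions) != ncol(prof))
    stop("proportions columns must match reference cell types")
  if (!is.null(colnames(proportions))) {
    if (!setequal(colnames(proportions), colnames(prof)))
      stop("proportion column names must match reference cell types")
    proportions <- proportions[, colnames(prof), drop = FALSE]
  } else colnames(proportions) <- colnames(prof)
  if (any(abs(rowSums(proportions) - 1) > 1e-8))
    stop("each proportion row must sum to 1")
  clean <- prof %*% t(proportions)
  colnames(clean) <- sprintf("mix%03d", seq_len(nrow(proportions)))
  mixture <- clean
  if (!is.na(snr))
    mixture <- clean + rnorm(length(clean), mean = 0, sd = abs(clean) / snr)
  rownames(proportions) <- colnames(mixture)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(mixture = mixture),
    colData = S4Vectors::DataFrame(proportions),
    metadata = list(snr = unname(snr), cellMap = refs$cellMap,
                    fold = refs$fold))
  as(se, "MixtureExperiment")
}

#' Synthetic tumor cohort with three planted infiltration classes
#'
#' Emulates a cohort whose immune decomposition separates into (1) a
#' T cell enriched class overexpressing T cell subset, antigen presenting
#' machinery and checkpoint-target genes, (2) a heterogeneously infiltrated
#' class overexpressing angiogenesis genes with a variable per-sample
#' degree of immune gene elevation, and (3) a non-infiltrated baseline
#' class. Expression is log-normal around per-gene baselines with
#' log-scale sample noise; \code{effect} is the log-scale elevation of the
#' planted genes (multiplier \code{exp(effect)}); \code{effect = 0}
#' collapses the three classes into one distribution.
#'
#' @param nPerClass integer vector of 3 class sizes.
#' @param collection signature collection providing the T cell subset
#'   gene lists; defaults to the packaged 24-signature collection.
#' @param effect nonnegative log-scale class effect (default 2).
#' @param p number of genes in the universe (default 10000).
#' @param sampleSd log-scale within-class noise sd (default 0.25).
#' @param seed optional integer seed.
#' @return list with \code{expr} (p x n matrix), \code{labels} (integer
#'   vector: 1 = T cell enriched, 2 = heterogeneously infiltrated,
#'   3 = non-infiltrated).
#' @export
makeClusteredCohort <- function(nPerClass = c(15L, 60L, 25L),
                                collection = builtinSignatures("bindea24"),
                                effect = 2, p = 10000L, sampleSd = 0.25,
                                seed = NULL) {
  stopifnot(length(nPerClass) == 3L, all(nPerClass >= 1L), effect >= 0)
  if (!is.null(seed)) set.seed(seed)
  tis <- tisDefinition()
  tGenes <- unique(unlist(lapply(tis@constituents, function(nm)
    signatureGenes(collection, nm))))
  apmGenes <- signatureGenes(builtinSignatures("apm"), "APM")
  ckpt <- builtinSignatures("checkpoint_targets")
  ckptGenes <- unlist(lapply(ckpt@signatures, slot, "genes"))
  angioGenes <- signatureGenes(builtinSignatures("angiogenesis"),
                               "Angiogenesis")
  immuneUp <- unique(c(tGenes, apmGenes, ckptGenes))
  allSig <- unique(c(unlist(lapply(collection@signatures, slot, "genes")),
                     apmGenes, ckptGenes, angioGenes))
  if (p < length(allSig))
    stop("'p' must cover all signature genes")
  genes <- c(allSig, sprintf("filler%05d", seq_len(p - length(allSig))))
  n <- sum(nPerClass)
  labels <- rep(1:3, times = nPerClass)
  baseline <- rlnorm(p, meanlog = 3, sdlog = 1)
  logExpr <- matrix(log(baseline), p, n) +
    matrix(rnorm(p * n, sd = sampleSd), p, n)
  iImmune <- match(immuneUp, genes)
  iAngio <- match(angioGenes, genes)
  for (j in which(labels == 1L))
    logExpr[iImmune, j] <- logExpr[iImmune, j] + effect
  for (j in which(labels == 2L)) {
    logExpr[iAngio, j] <- logExpr[iAngio, j] + effect
    # heterogeneous partial immune elevation, sample-specific, sitting
    # between the enriched (effect) and baseline (0) classes
    logExpr[iImmune, j] <- logExpr[iImmune, j] +
      runif(1, effect / 4, effect / 2)
  }
  expr <- exp(logExpr)
  dimnames(expr) <- list(genes, sprintf("sample%03d", seq_len(n)))
  list(expr = expr, labels = labels)
}

#' Synthetic methylation cohort with known leukocyte fractions
#'
#' Implements the two-component generative model for tumor methylation:
#' per probe, a leukocyte representative beta B_k and a cancer beta C_k are
#' drawn with bimodal separation (half the probes leukocyte-hypermethylated
#' relative to cancer, half the reverse), and each tumor sample's beta at
#' probe k is f_i * B_k + (1 - f_i) * C_k plus Gaussian noise, clipped to
#' [0,1] (beta values are proportions by definition). Leukocyte reference
#' samples are noisy replicates around B_k.
#'
#' @param nTumors number of tumor samples (ignored when
#'   \code{trueFractions} is given).
#' @param nProbes number of probes (at least 2000, so the top+bottom 1000
#'   extreme-probe signature is constructible).
#' @param trueFractions per-tumor leukocyte fractions in [0,1]; defaults to
#'   \code{runif(nTumors, 0.05, 0.6)}.
#' @param noiseSd Gaussian noise sd on beta values (default 0.05).
#' @param nRefSamples number of leukocyte reference samples (default 6).
#' @param separation mean |B_k - C_k| separation of the bimodal probe
#'   design (default 0.7, the scale of difference seen at the extreme
#'   probes such a signature selects).
#' @param nAnchors number of near-pure (f = 0) anchor tumors appended to
#'   the cohort (default 2). Sizable tumor cohorts contain nearly pure
#'   samples, and the purest-tumor anchor T_k of the downstream estimator
#'   is only identifiable when some exist; a cohort without them yields
#'   fractions relative to its least infiltrated sample.
#' @param seed optional integer seed.
#' @return a \linkS4class{SyntheticBetaCohort}; the anchor samples are the
#'   last \code{nAnchors} columns, with \code{trueFractions} entries of 0.
#' @export
makeMethylationCohort <- function(nTumors = 20L, nProbes = 10000L,
                                  trueFractions = NULL, noiseSd = 0.05,
                                  nRefSamples = 6L, separation = 0.7,
                                  nAnchors = 2L, seed = NULL) {
  if (nProbes < 2000L)
    stop("'nProbes' must be >= 2000 (extreme-probe signature needs top+bottom 1000)")
  stopifnot(noiseSd >= 0, separation > 0, separation < 1, nAnchors >= 0L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trueFractions)) trueFractions <- runif(nTumors, 0.05, 0.6)
  stopifnot(all(trueFractions >= 0 & trueFractions <= 1))
  trueFractions <- c(trueFractions, rep(0, nAnchors))
  nTumors <- length(trueFractions)
  lo <- (1 - separation) / 2
  hi <- 1 - lo
  half <- nProbes %/% 2L
  leukHigh <- c(rep(TRUE, half), rep(FALSE, nProbes - half))
  B <- ifelse(leukHigh, runif(nProbes, hi - 0.05, hi + 0.05),
              runif(nProbes, lo - 0.05, lo + 0.05))
  C <- ifelse(leukHigh, runif(nProbes, lo - 0.05, lo + 0.05),
              runif(nProbes, hi - 0.05, hi + 0.05))
  B <- pmin(pmax(B, 0), 1)
  C <- pmin(pmax(C, 0), 1)
  probes <- sprintf("cg%06d", seq_len(nProbes))
  clean <- outer(B, trueFractions) + outer(C, 1 - trueFractions)
  tumor <- clean
  if (noiseSd > 0)
    tumor <- tumor + rnorm(length(tumor), sd = noiseSd)
  tumor <- pmin(pmax(tumor, 0), 1)
  dimnames(tumor) <- list(probes, sprintf("tumor%03d", seq_len(nTumors)))
  ref <- matrix(B, nProbes, nRefSamples)
  if (noiseSd > 0)
    ref <- ref + rnorm(length(ref), sd = noiseSd)
  ref <- pmin(pmax(ref, 0), 1)
  dimnames(ref) <- list(probes, sprintf("pbmc%02d", seq_len(nRefSamples)))
  new("SyntheticBetaCohort", tumorBetas = tumor, referenceBetas = ref,
      trueFractions = trueFractions)
}
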