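test_that("uniform-spacings proportions sum to one with the stated deterministic transform", {
  p <- simulateMixingProportions(500, k = 5, seed = 31)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p > 0 & p < 1))
  # stated internal draws map to the stated proportions
  expect_equal(immunedecomp:::.spacings(c(0.2, 0.5, 0.7, 0.9)),
               c(0.2, 0.3, 0.2, 0.2, 0.1), tolerance = 1e-12)
  # unsorted input is sorted first
  expect_equal(immunedecomp:::.spacings(c(0.9, 0.2, 0.7, 0.5)),
               c(0.2, 0.3, 0.2, 0.2, 0.1), tolerance = 1e-12)
  expect_error(simulateMixingProportions(5, k = 1), "k")
})

test_that("spacings have symmetric means and Beta(1, k-1) marginals", {
  p <- simulateMixingProportions(10000, k = 5, seed = 32)
  expect_true(all(abs(colMeans(p) - 0.2) < 0.01))
  ks <- apply(p, 2, function(x)
    suppressWarnings(stats::ks.test(x, stats::pbeta, 1, 4)$p.value))
  expect_true(all(ks > 0.01))
})

test_that("reference profiles overexpress each cell type's own signature genes", {
  b <- builtinSignatures("bindea24")
  refs <- makeReferenceProfiles(b, p = 3000, fold = 5, seed = 33)
  expect_equal(dim(refs$profiles), c(3000L, 5L))
  expect_true("CD45neg" %in% colnames(refs$profiles))
  for (ct in names(refs$cellMap)) {
    own <- signatureGenes(b, refs$cellMap[[ct]])
    for (other in setdiff(colnames(refs$profiles), ct))
      expect_gt(mean(refs$profiles[own, ct]),
                mean(refs$profiles[own, other]))
  }
  # CD45neg never overexpresses signature genes: identical to baseline of
  # every other profile outside that profile's own signature
  sig <- signatureGenes(b, refs$cellMap[["NK"]])
  expect_equal(refs$profiles[sig, "CD45neg"], refs$profiles[sig, "CD8_T"])
  expect_error(
    makeReferenceProfiles(b,
      cellMap = c(a = "NK cells", b = "NK CD56dim cells"), p = 3000),
    "share")
})

test_that("mixtures are exact linear combinations; one-hot rows reproduce profiles", {
  b <- builtinSignatures("bindea24")
  refs <- makeReferenceProfiles(b, p = 2500, seed = 34)
  k <- ncol(refs$profiles)
  onehot <- diag(k)
  colnames(onehot) <- colnames(refs$profiles)
  clean <- mixAndAddNoise(refs, onehot, snr = NA)
  mix <- SummarizedExperiment::assay(clean, "mixture")
  for (j in seq_len(k))
    expect_equal(unname(mix[, j]), unname(refs$profiles[, j]))
  expect_true(is.na(snrLevel(clean)))

  # linear in proportions when noiseless
  p1 <- simulateMixingProportions(4, k = k, seed = 35)
  p2 <- simulateMixingProportions(4, k = k, seed = 36)
  colnames(p1) <- colnames(p2) <- colnames(refs$profiles)
  m1 <- SummarizedExperiment::assay(mixAndAddNoise(refs, p1), "mixture")
  m2 <- SummarizedExperiment::assay(mixAndAddNoise(refs, p2), "mixture")
  m12 <- SummarizedExperiment::assay(
    mixAndAddNoise(refs, (p1 + p2) / 2), "mixture")
  expect_equal(m12, (m1 + m2) / 2, tolerance = 1e-12)

  bad <- p1[, -1]
  expect_error(mixAndAddNoise(refs, bad), "cell types")
})

test_that("injected noise has standard deviation value/S", {
  b <- builtinSignatures("bindea24")
  refs <- makeReferenceProfiles(b, p = 200, seed = 37)
  # 10^4 samples with identical proportions give replicate noisy draws of
  # each gene's fixed clean value
  prop <- matrix(0.2, 10000, 5,
                 dimnames = list(NULL, colnames(refs$profiles)))
  clean <- SummarizedExperiment::assay(
    mixAndAddNoise(refs, prop[1, , drop = FALSE]), "mixture")[, 1]
  S <- 4
  noisy <- SummarizedExperiment::assay(
    mixAndAddNoise(refs, prop, snr = S, seed = 38), "mixture")
  for (g in c(10L, 50L, 150L)) {
    v <- clean[[g]]
    expect_equal(sd(noisy[g, ] - v), v / S, tolerance = 0.03)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(simulateMixingProportions(20, seed = 39),
                   simulateMixingProportions(20, seed = 39))
  b <- builtinSignatures("bindea24")
  r1 <- makeReferenceProfiles(b, p = 2200, seed = 40)
  r2 <- makeReferenceProfiles(b, p = 2200, seed = 40)
  expect_identical(r1$profiles, r2$profiles)
  pr <- simulateMixingProportions(5, seed = 41)
  colnames(pr) <- colnames(r1$profiles)
  expect_identical(
    SummarizedExperiment::assay(mixAndAddNoise(r1, pr, snr = 2, seed = 42)),
    SummarizedExperiment::assay(mixAndAddNoise(r2, pr, snr = 2, seed = 42)))
  c1 <- makeMethylationCohort(5, 2000, seed = 43)
  c2 <- makeMethylationCohort(5, 2000, seed = 43)
  expect_identical(c1@tumorBetas, c2@tumorBetas)
})

test_that("planted-class cohorts have the requested sizes and labels", {
  cc <- makeClusteredCohort(c(4L, 6L, 5L), effect = 2, p = 2000,
                            seed = 44)
  expect_equal(ncol(cc$expr), 15L)
  expect_equal(as.vector(table(cc$labels)), c(4L, 6L, 5L))
  # T cell / APM / checkpoint genes elevated in class 1 vs class 3
  apm <- signatureGenes(builtinSignatures("apm"), "APM")
  expect_gt(mean(log(cc$expr[apm, cc$labels == 1])),
            mean(log(cc$expr[apm, cc$labels == 3])) + 1)
})

test_that("methylation cohorts hit the exact noiseless endpoints", {
  coh1 <- makeMethylationCohort(trueFractions = c(1, 1), nProbes = 2000,
                                noiseSd = 0, seed = 45)
  # f = 1: tumor equals leukocyte reference exactly
  expect_equal(unname(coh1@tumorBetas[, 1]),
               unname(coh1@referenceBetas[, 1]))
  coh0 <- makeMethylationCohort(trueFractions = 0, nProbes = 2000,
                                noiseSd = 0, seed = 46)
  # f = 0: tumor equals the cancer component, far from leukocyte betas
  expect_gt(mean(abs(coh0@tumorBetas[, 1] - coh0@referenceBetas[, 1])),
            0.4)
  expect_true(all(coh0@tumorBetas >= 0 & coh0@tumorBetas <= 1))
  expect_error(makeMethylationCohort(5, nProbes = 1500), "2000")
})
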