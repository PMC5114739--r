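test_that("extreme-probe signature ranks probes by leukocyte-tumor difference", {
  probes <- sprintf("cg%04d", 1:6)
  # probe 1 strongly leukocyte-high, probe 6 strongly leukocyte-low
  leuk <- matrix(c(0.9, 0.8, 0.55, 0.45, 0.2, 0.1), 6, 3,
                 dimnames = list(probes, paste0("r", 1:3)))
  tum <- matrix(c(0.1, 0.2, 0.5, 0.5, 0.8, 0.9), 6, 4,
                dimnames = list(probes, paste0("t", 1:4)))
  tum[1, ] <- c(0.1, 0.15, 0.3, 0.12)
  sig <- buildLeukocyteSignature(tum, leuk, nTop = 2)
  expect_identical(sig@probesHigh, c("cg0001", "cg0002"))
  expect_identical(sig@probesLow, c("cg0006", "cg0005"))
  # T_k is the min tumor beta on L_h probes and the max on L_l probes
  expect_equal(unname(sig@tumorAnchorBeta["cg0001"]), 0.1)
  expect_equal(unname(sig@tumorAnchorBeta["cg0006"]), 0.9)
  expect_equal(unname(sig@leukocyteBeta["cg0001"]), 0.9)

  expect_error(buildLeukocyteSignature(tum, leuk, nTop = 1000),
               "shared probes")
})

test_that("per-probe fractions follow the closed-form inversion exactly", {
  sig <- new("LeukocyteSignature",
             probesHigh = c("h1", "h2"), probesLow = "l1",
             leukocyteBeta = c(h1 = 0.9, h2 = 0.8, l1 = 0.1),
             tumorAnchorBeta = c(h1 = 0.1, h2 = 0.2, l1 = 0.8))
  col <- c(h1 = 0.5, h2 = 0.05, l1 = 0.8)
  f <- probeFractions(sig, col)
  expect_equal(unname(f["h1"]), 0.5)           # (0.5-0.1)/(0.9-0.1)
  expect_equal(unname(f["h2"]), -0.25)         # below anchor: retained
  expect_equal(unname(f["l1"]), 0)             # T_ik = T_k
  expect_equal(unname(probeFractions(sig, c(h1 = 0.9, h2 = 0.8,
                                            l1 = 0.1))),
               c(1, 1, 1))                     # T_ik = B_k
  expect_error(probeFractions(sig, c(h1 = 0.5)), "missing")
})

test_that("the sample fraction is the global density mode on the fixed grid", {
  # degenerate point mass bypasses the KDE
  expect_equal(leukocyteFraction(rep(0.3, 100)), 0.3)
  expect_error(leukocyteFraction(rep(0.3, 10)), "too few")

  # bimodal mixture: the global, not local, maximum wins
  set.seed(61)
  fik <- c(rnorm(1900, 0.4, 0.03), rnorm(100, 0.9, 0.03))
  expect_equal(leukocyteFraction(fik), kdeModeOracle(fik))
  expect_equal(leukocyteFraction(fik), 0.4, tolerance = 0.02)

  # permutation invariance
  set.seed(62)
  x <- rnorm(500, 0.5, 0.1)
  expect_identical(leukocyteFraction(x), leukocyteFraction(sample(x)))
})

test_that("known leukocyte fractions are recovered from noisy synthetic cohorts", {
  truth <- c(0.1, 0.3, 0.5, 0.7)
  coh <- makeMethylationCohort(trueFractions = truth, nProbes = 10000,
                               noiseSd = 0.05, seed = 63)
  sig <- buildLeukocyteSignature(coh@tumorBetas, coh@referenceBetas)
  est <- estimateLeukocyteFractions(sig, coh@tumorBetas)
  expect_true(all(abs(est$fraction[seq_along(truth)] - truth) <= 0.05))
  expect_true(all(est$nProbesUsed >= 1900))
  expect_true(all(est$shareOutOfRange >= 0 & est$shareOutOfRange <= 1))
})

test_that("noiseless well-separated mixtures are recovered to grid resolution", {
  truth <- c(0.2, 0.45, 0.8)
  coh <- makeMethylationCohort(trueFractions = truth, nProbes = 4000,
                               noiseSd = 0, separation = 0.6, seed = 64)
  sig <- buildLeukocyteSignature(coh@tumorBetas, coh@referenceBetas,
                                 nTop = 1000)
  est <- estimateLeukocyteFractions(sig, coh@tumorBetas)
  expect_true(all(abs(est$fraction[seq_along(truth)] - truth) <= 0.0015))
})

test_that("methylation fractions track an expression-based IIS on a shared cohort", {
  # one latent infiltration level drives both data types
  set.seed(65)
  n <- 24
  latent <- runif(n, 0.05, 0.7)
  coh <- makeMethylationCohort(trueFractions = latent, nProbes = 4000,
                               noiseSd = 0.05)
  sig <- buildLeukocyteSignature(coh@tumorBetas, coh@referenceBetas)
  fhat <- estimateLeukocyteFractions(sig,
            coh@tumorBetas)$fraction[seq_len(n)]

  b <- builtinSignatures("bindea24")
  iis <- iisDefinition()
  allGenes <- unique(unlist(lapply(b@signatures, slot, "genes")))
  p <- 3000
  genes <- c(allGenes, sprintf("filler%05d", seq_len(p - length(allGenes))))
  baseline <- rlnorm(p, 3, 1)
  expr <- matrix(baseline, p, n, dimnames = list(genes,
                 sprintf("s%02d", seq_len(n))))
  idx <- match(unique(unlist(lapply(iis@constituents, function(nm)
    signatureGenes(b, nm)))), genes)
  for (j in seq_len(n))
    expr[idx, j] <- expr[idx, j] * (1 + 4 * latent[j])
  expr <- expr * exp(matrix(rnorm(p * n, 0, 0.2), p, n))
  z <- standardizeScores(ssgseaScores(expr, b, normalize = FALSE))
  iisScore <- aggregateScore(z, iis)
  expect_gt(cor(fhat, iisScore, method = "spearman"), 0.6)
})
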