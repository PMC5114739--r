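test_that("per-sample rank transform gives ascending ranks with averaged ties", {
  m <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  expect_equal(unname(rankTransform(m)[, 1]), c(5, 4, 3, 2, 1))

  m2 <- matrix(c(2, 2, 1), ncol = 1,
               dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(rankTransform(m2)[, 1]), c(2.5, 2.5, 1))

  # strictly increasing transforms leave ranks unchanged
  m3 <- randomExpr(40, 3, seed = 5)
  expect_equal(rankTransform(m3), rankTransform(log1p(m3)))
  expect_equal(rankTransform(m3), rankTransform(m3^3))
})

test_that("enrichment score matches the hand-evaluated running sum", {
  r <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  expected <- 5^0.25 / (5^0.25 + 4^0.25) + 1 + 2 / 3 + 1 / 3 + 0
  expect_equal(enrichmentScore(r, c("g1", "g2"), alpha = 0.25), expected,
               tolerance = 1e-12)
  # alpha = 0 closed form: top-1 gene of p = 2
  expect_equal(enrichmentScore(c(a = 2, b = 1), "a", alpha = 0), 1)
})

test_that("sets at the top of the ranking outscore sets at the bottom", {
  m <- randomExpr(30, 1, seed = 7)
  r <- rankTransform(m)[, 1]
  top <- names(sort(r, decreasing = TRUE))[1:4]
  bottom <- names(sort(r))[1:4]
  expect_gt(enrichmentScore(r, top), enrichmentScore(r, bottom))
})

test_that("fast evaluation equals the brute-force running-sum oracle on small instances", {
  set.seed(42)
  for (rep in 1:60) {
    p <- sample(3:8, 1)
    n <- sample(1:3, 1)
    m <- sample(1:min(3, p - 1), 1)
    expr <- matrix(sample(seq_len(p * n) / 2, p * n), p, n,
                   dimnames = list(sprintf("g%02d", seq_len(p)),
                                   sprintf("s%02d", seq_len(n))))
    if (rep %% 3 == 0) expr[sample(length(expr), 2)] <- expr[1] # ties
    geneSet <- sample(rownames(expr), m)
    alpha <- sample(c(0, 0.25, 1), 1)
    sc <- SignatureCollection(list(GeneSignature("S", geneSet)))
    fast <- ssgseaScores(expr, sc, alpha = alpha, normalize = FALSE)
    for (j in seq_len(n)) {
      brute <- bruteEnrichmentScore(expr[, j], rownames(expr), geneSet,
                                    alpha)
      expect_equal(unname(fast[1, j]), brute, tolerance = 1e-10)
      expect_equal(enrichmentScore(rankTransform(expr)[, j], geneSet,
                                   alpha = alpha),
                   brute, tolerance = 1e-10)
    }
  }
})

test_that("scores are invariant under strictly monotone per-sample transforms", {
  m <- randomExpr(100, 5, seed = 8)
  sc <- SignatureCollection(list(GeneSignature("A", rownames(m)[1:6]),
                                 GeneSignature("B", rownames(m)[7:9])))
  s1 <- ssgseaScores(m, sc, normalize = FALSE)
  s2 <- ssgseaScores(exp(m / max(m) * 4), sc, normalize = FALSE)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("random equal-sized signatures share one expected score on exchangeable data", {
  set.seed(9)
  m <- randomExpr(60, 8)
  means <- replicate(500, {
    sc <- SignatureCollection(list(GeneSignature("R",
      sample(rownames(m), 5))))
    mean(ssgseaScores(m, sc, normalize = FALSE))
  })
  # the expectation is common to every size-5 signature: two disjoint
  # batches of draws must agree within Monte-Carlo error
  h1 <- means[1:250]
  h2 <- means[251:500]
  se <- sd(means) / sqrt(250)
  expect_lt(abs(mean(h1) - mean(h2)), 4 * se)
  # and a signature built from any fixed gene subset estimates the same
  fixed <- mean(ssgseaScores(m, SignatureCollection(list(
    GeneSignature("F", rownames(m)[1:5]))), normalize = FALSE))
  expect_lt(abs(fixed - mean(means)), 4 * sd(means))
})

test_that("global range normalization and column permutation behave as documented", {
  m <- randomExpr(80, 6, seed = 10)
  sc <- SignatureCollection(list(GeneSignature("A", rownames(m)[1:5]),
                                 GeneSignature("B", rownames(m)[10:14])))
  norm <- ssgseaScores(m, sc, normalize = TRUE)
  expect_equal(max(norm) - min(norm), 1, tolerance = 1e-12)

  raw <- ssgseaScores(m, sc, normalize = FALSE)
  one <- ssgseaScores(m[, 1, drop = FALSE],
                      SignatureCollection(list(sc[["A"]])),
                      normalize = FALSE)
  expect_equal(unname(one[1, 1]), unname(raw["A", 1]))

  perm <- sample(ncol(m))
  expect_equal(ssgseaScores(m[, perm], sc, normalize = FALSE),
               raw[, perm])
})

test_that("degenerate signatures raise informative errors", {
  m <- randomExpr(20, 2, seed = 12)
  none <- SignatureCollection(list(GeneSignature("gone", c("x1", "x2"))))
  expect_error(suppressWarnings(ssgseaScores(m, none)), "gone")
  all <- SignatureCollection(list(GeneSignature("all", rownames(m))))
  expect_error(ssgseaScores(m, all), "universe")
  some <- SignatureCollection(list(GeneSignature("partial",
    c(rownames(m)[1:2], "absent"))))
  expect_warning(es <- ssgseaScores(m, some, normalize = FALSE), "absent")
  expect_true(all(is.finite(es)))
  expect_error(
    suppressWarnings(ssgseaScores(m, some, minGenesPresent = 3L)),
    "partial")
})
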