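test_that("sample ranking is descending with a lexicographic tie-break", {
  expect_identical(rankSample(c(5, 1, 3), c("A", "B", "C")),
                   c("A", "C", "B"))
  expect_identical(rankSample(c(2, 2), c("B", "A")), c("A", "B"))
  expect_error(rankSample(3, "A"), ">= 2 genes")
  expect_error(rankSample(c(1, NaN), c("A", "B")), "non-finite")
})

test_that("running-sum statistic reproduces hand-enumerated values", {
  u <- c("g1", "g2", "g3", "g4")
  expect_equal(enrichmentStatistic(u, c("g1", "g2")), 1)
  expect_equal(enrichmentStatistic(u, c("g1", "g3")), 0.5)
  expect_equal(enrichmentStatistic(u, c("g3", "g4")), -1)
  expect_error(enrichmentStatistic(u, c("x1")), "intersect")
  expect_error(enrichmentStatistic(u, u), "universe")
})

test_that("statistic equals the naive running-sum loop on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    m <- sample(1:min(10, n - 1), 1)
    order <- sample(sprintf("g%02d", 1:n))
    sig <- sample(order, m)
    expect_identical(enrichmentStatistic(order, sig), naiveES(order, sig))
  }
})

test_that("exhaustive permutation z matches full enumeration", {
  # the 4-choose-2 case has null ES (1, .5, .5, -.5, -.5, -1): mean 0,
  # population sd sqrt(0.5), so the top placement scores z = sqrt(2)
  r <- permutationNormalize(1, 4, 2)
  expect_true(r$exhaustive)
  expect_equal(r$z, sqrt(2), tolerance = 1e-12)
  expect_equal(permutationNormalize(0, 4, 2)$z, 0)

  set.seed(7)
  for (i in 1:40) {
    n <- sample(6:14, 1)
    m <- sample(2:4, 1)
    order <- sample(sprintf("g%02d", 1:n))
    sig <- sample(order, m)
    es <- enrichmentStatistic(order, sig)
    z <- permutationNormalize(es, n, m)$z
    expect_equal(z, naiveExhaustiveZ(order, sig), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo normalization is seeded and reproducible", {
  z1 <- permutationNormalize(0.3, 500, 20, nPerm = 200, seed = 11)
  z2 <- permutationNormalize(0.3, 500, 20, nPerm = 200, seed = 11)
  expect_identical(z1$z, z2$z)
  expect_false(z1$exhaustive)
  expect_error(permutationNormalize(0.3, 500, 20, nPerm = 50, seed = 1),
               "nPerm >= 100")
})

test_that("scoreSignature drops absent genes and is deterministic", {
  m <- randomExprMatrix(100, 4, seed = 3)
  sig <- GeneSignature("test", c(rownames(m)[1:8], "ABSENT1", "ABSENT2"))
  expect_message(z <- scoreSignature(m, sig, nPerm = 200, seed = 5),
                 "2 gene\\(s\\) absent")
  expect_named(z, colnames(m))
  expect_identical(z, suppressMessages(
    scoreSignature(m, sig, nPerm = 200, seed = 5)))

  # identical samples get identical scores
  m2 <- cbind(m[, 1, drop = FALSE], m[, 1, drop = FALSE])
  colnames(m2) <- c("a", "b")
  z2 <- scoreSignature(m2, GeneSignature("t", rownames(m)[1:8]),
                       nPerm = 200, seed = 5)
  expect_identical(z2[["a"]], z2[["b"]])

  expect_error(scoreSignature(m, GeneSignature("none", c("X1", "X2"))),
               "no genes")
  expect_error(
    suppressMessages(scoreSignature(m, GeneSignature("few", c(rownames(m)[1:2], "NOPE")))),
    "< 5 required")
})

test_that("PBM is the sign-flipped plasma z and oriented by construction", {
  z <- matrix(c(1.4142, -0.3, 0), 1, 3,
              dimnames = list("s1", c("PlasmaB", "CD8T", "NK")))
  sc <- computePBM(z, "PlasmaB")
  expect_equal(unname(pbmScores(sc)), -1.4142)
  expect_equal(unname(pbmScores(computePBM(z * 0, "PlasmaB"))), 0)
  expect_error(computePBM(z, "Missing"), "not among")
  # configurable sign convention
  expect_equal(unname(pbmScores(computePBM(z, "PlasmaB", flipSign = FALSE))),
               1.4142)

  # plasma markers forced to the bottom ranks give a positive PBM
  set.seed(9)
  m <- randomExprMatrix(60, 1, seed = 9)
  sig <- rownames(m)[1:10]
  m[sig, 1] <- min(m) - 1:10
  zz <- scoreSignature(m, GeneSignature("PlasmaB", sig), nPerm = 500, seed = 2)
  expect_true(-zz[[1]] > 0)
})

test_that("PBM is invariant to strictly monotone transforms of expression", {
  m <- randomExprMatrix(200, 5, seed = 12)
  m <- m + 10  # keep positive for log/sqrt
  sig <- GeneSignature("PlasmaB", rownames(m)[1:15])
  z0 <- scoreSignature(m, sig, nPerm = 300, seed = 4)
  for (f in list(function(x) 2 * x + 1, log, sqrt, function(x) x^3)) {
    expect_equal(scoreSignature(f(m), sig, nPerm = 300, seed = 4), z0)
  }
})

test_that("down-shifting plasma markers monotonically raises PBM", {
  set.seed(31)
  base <- randomExprMatrix(400, 1, seed = 31)
  sig <- rownames(base)[1:25]
  shifts <- seq(0, 4, length.out = 15)
  pbm <- vapply(shifts, function(s) {
    m <- base
    m[sig, 1] <- m[sig, 1] - s
    -scoreSignature(m, GeneSignature("PlasmaB", sig),
                    nPerm = 300, seed = 6)[[1]]
  }, 0)
  expect_gt(cor(shifts, pbm, method = "spearman"), 0.95)
})

test_that("the weighted variant changes the statistic only when enabled", {
  m <- randomExprMatrix(80, 3, seed = 8)
  sig <- GeneSignature("t", rownames(m)[1:10])
  z0 <- scoreSignature(m, sig, nPerm = 200, seed = 2, weightExponent = 0)
  z1 <- scoreSignature(m, sig, nPerm = 200, seed = 2, weightExponent = 1)
  expect_false(isTRUE(all.equal(z0, z1)))
  # alpha = 0 is the unweighted statistic
  expect_identical(z0, scoreSignature(m, sig, nPerm = 200, seed = 2))
})
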