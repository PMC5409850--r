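test_that("paired permutation test honours its contract on degenerate input", {
  a <- c(0.5, 0.6, 0.7, 0.4)
  # identical conditions: observed 0, p = 1 under smoothing
  r <- pairedPermutationTest(a, a, nPerm = 500, seed = 1)
  expect_equal(observedStat(r), 0)
  expect_equal(pValue(r), 1)

  expect_error(pairedPermutationTest(a, a[1:3]), "paired")
  expect_error(pairedPermutationTest(1, 2), "at least 2")

  # default permutation count is 10,000
  expect_identical(formals(pairedPermutationTest)$nPerm, 10000L)

  # deterministic given the seed
  b <- a + c(0.05, -0.02, 0.07, 0.01)
  r1 <- pairedPermutationTest(a, b, nPerm = 2000, seed = 7)
  r2 <- pairedPermutationTest(a, b, nPerm = 2000, seed = 7)
  expect_identical(pValue(r1), pValue(r2))
  expect_identical(nullValues(r1), nullValues(r2))
})

test_that("Monte-Carlo p matches exact sign-flip enumeration", {
  # n = 9 pairs, all differences positive and equal
  d <- rep(0.1, 9)
  a <- seq(0.1, 0.9, by = 0.1) + d
  b <- seq(0.1, 0.9, by = 0.1)
  pExactOracle <- exactSignFlipP(d)        # bit-mask enumeration, 512 patterns
  expect_equal(pExactOracle, 2 / 512)      # only the two all-equal patterns

  rExact <- pairedPermutationTest(a, b, exact = TRUE)
  expect_equal(pValue(rExact), pExactOracle)
  expect_true(rExact@exact)
  expect_equal(rExact@nPerm, 512L)

  rMc <- pairedPermutationTest(a, b, nPerm = 10000, seed = 3)
  expect_lt(abs(pValue(rMc) - pExactOracle),
            3 * sqrt(pExactOracle * (1 - pExactOracle) / 10000) + 2e-4)

  # a mixed-sign case against the same oracle
  set.seed(21)
  d2 <- rnorm(8, 0.03, 0.05)
  r2 <- pairedPermutationTest(d2, rep(0, 8), exact = TRUE)
  expect_equal(pValue(r2), exactSignFlipP(d2))
})

test_that("chance null resamples the pool with replacement, deterministically", {
  mesh <- makeStripMesh(120)
  ref <- RoiLabel("g", "mroi1", "left", 0:9, mesh)

  # degenerate pool: every element overlaps identically -> zero-width CI
  pool <- makeOverlapPool(mesh, 0:9, rep(0.4, 12))
  null <- chanceOverlapNull(ref, pool, nIter = 300, seed = 5)
  expect_equal(chanceMean(null), 0.4)
  expect_equal(unname(chanceCI(null)), c(0.4, 0.4))

  # default iteration count is 1000
  expect_identical(formals(chanceOverlapNull)$nIter, 1000L)

  n1 <- chanceOverlapNull(ref, pool, nIter = 100, seed = 9)
  n2 <- chanceOverlapNull(ref, pool, nIter = 100, seed = 9)
  expect_identical(nullValues(n1), nullValues(n2))

  expect_error(chanceOverlapNull(ref, list(), nIter = 10), "empty")
})

test_that("null mean converges to the enumerated grand mean of an 80-label pool", {
  mesh <- makeStripMesh(120)
  ref <- RoiLabel("g", "mroi1", "left", 0:9, mesh)
  overlaps <- rep(seq(0, 1, by = 0.1), length.out = 80)  # hand-set, multiples of 1/10
  pool <- makeOverlapPool(mesh, 0:9, overlaps)
  grandMean <- mean(overlaps)  # full enumeration of the pool
  null <- chanceOverlapNull(ref, pool, nIter = 1000, seed = 12)
  se <- sd(overlaps) / sqrt(1000)
  expect_lt(abs(chanceMean(null) - grandMean), 3 * se)
  # batch-mean mode converges to the same grand mean with a tighter spread
  nullB <- chanceOverlapNull(ref, pool, nIter = 1000, seed = 12, batchSize = 10)
  expect_lt(abs(chanceMean(nullB) - grandMean), 3 * se / sqrt(10) * 2)
  expect_lt(sd(nullValues(nullB)), sd(nullValues(null)))
})

test_that("exceedance p behaves at the extremes and the median", {
  mesh <- makeStripMesh(400)
  ref <- RoiLabel("g", "m", "left", 0:79, mesh)
  # 80 pool elements with distinct overlaps, so the median is not a heavy tie
  pool <- makeOverlapPool(mesh, 0:79, (0:79) / 80)
  null <- chanceOverlapNull(ref, pool, nIter = 1000, seed = 2)
  expect_equal(chanceExceedanceP(0.999, null), 1 / 1001)
  expect_equal(chanceExceedanceP(-0.01, null), 1)
  pMid <- chanceExceedanceP(median(nullValues(null)), null)
  expect_lt(abs(pMid - 0.5), 0.1)
})

test_that("exceedance p is uniform-or-conservative under a true null", {
  mesh <- makeStripMesh(400)
  ref <- RoiLabel("g", "m", "left", 0:79, mesh)
  pool <- makeOverlapPool(mesh, 0:79, (0:79) / 80)
  achieved <- vapply(pool, function(l) overlapProportion(ref, l), numeric(1))
  set.seed(61)
  ps <- vapply(1:500, function(i) {
    observed <- sample(achieved, 1)  # a draw from the null itself
    null <- chanceOverlapNull(ref, pool, nIter = 400, seed = 70000 + i)
    chanceExceedanceP(observed, null)
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_lte(mean(ps <= 0.2), 0.25)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroniCorrect(0.004, 8), 0.032)
  expect_equal(bonferroniCorrect(0.2, 8), 1)
  expect_equal(bonferroniCorrect(0.123, 1), 0.123)
  expect_equal(bonferroniCorrect(c(0.01, 0.5), 4), c(0.04, 1))
  expect_error(bonferroniCorrect(0.05, 0), ">= 1")
})

test_that("Friedman statistic follows the rank formula with tie correction", {
  # all blocks identical across treatments: statistic 0, p 1
  tied <- matrix(5, nrow = 4, ncol = 3)
  r <- friedmanTest(tied)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # k = 2, one treatment uniformly larger: statistic = n
  for (n in c(3, 5, 10)) {
    m <- cbind(rep(1, n), rep(2, n))
    expect_equal(friedmanTest(m)$statistic, n)
    expect_equal(friedmanTest(m)$df, 1L)
  }

  # invariant under strictly monotone transforms
  set.seed(17)
  x <- matrix(runif(15), nrow = 5)
  expect_equal(friedmanTest(x)$statistic, friedmanTest(exp(x))$statistic)
  expect_equal(friedmanTest(x)$statistic, friedmanTest(x^3 + 2)$statistic)

  expect_error(friedmanTest(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(friedmanTest(matrix(1:4, ncol = 1)), "2 treatments")
})

test_that("Friedman agrees with stats::friedman.test on tie-free data", {
  set.seed(31)
  for (k in 2:3) {
    x <- matrix(rnorm(6 * k), nrow = 6)
    ours <- friedmanTest(x)
    base <- stats::friedman.test(x)
    expect_equal(ours$statistic, unname(base$statistic))
    expect_equal(ours$p.value, unname(base$p.value))
  }
})

test_that("Friedman p is consistent with a treatment-permutation oracle", {
  set.seed(43)
  # block counts large enough for the chi-square approximation to hold;
  # the permutation reference then pins both the statistic and the p scale
  for (dims in list(c(20, 2), c(15, 3), c(25, 3))) {
    x <- matrix(rnorm(prod(dims)), nrow = dims[1])
    pChisq <- friedmanTest(x)$p.value
    pPerm <- friedmanPermP(x, nPerm = 4000, seed = 7)
    expect_lt(abs(pChisq - pPerm), 0.1)
  }
})
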