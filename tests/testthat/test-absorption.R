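# hand-derived fundamental matrix of the baseline chain: the lower 2x2 of
# I - Q_t has determinant 0.5*0.66 - 0.5*0.33 = 0.165, giving visit counts
# 4 and 100/33 from iM
baselineFundamental <- rbind(
  pre_trauma  = c(1, 4, 100 / 33),
  iM          = c(0, 4, 100 / 33),
  reactivated = c(0, 2, 100 / 33))
colnames(baselineFundamental) <- rownames(baselineFundamental)

test_that("fundamental matrix of the baseline chain matches hand inversion", {
  N <- fundamentalMatrix(buildBaselineChain())
  expect_equal(N, baselineFundamental, tolerance = 1e-12)
})

test_that("expected absorption times are fundamental-matrix row sums", {
  q <- buildBaselineChain()
  expect_equal(expectedAbsorptionTime(q, "iM"), 232 / 33, tolerance = 1e-12)
  expect_equal(expectedAbsorptionTime(q, "pre_trauma"), 1 + 232 / 33,
               tolerance = 1e-12)
  expect_identical(expectedAbsorptionTime(q, "niM"), 0)
  ab <- absorptionSummary(q)
  expect_equal(unname(timeToAbsorption(ab)),
               unname(rowSums(fundamental(ab))), tolerance = 1e-14)
})

test_that("expected visit counts behave like occupation counts", {
  q <- buildBaselineChain()
  expect_equal(expectedVisits(q, "iM", "reactivated"), 100 / 33,
               tolerance = 1e-12)
  expect_equal(expectedVisits(q, "reactivated", "pre_trauma"), 0)
  set.seed(11)
  for (i in 1:10) {
    ch <- randomAbsorbingChain()
    N <- fundamentalMatrix(ch)
    expect_true(all(diag(N) >= 1 - 1e-12))
    expect_true(all(N >= -1e-12))
  }
  # a reactivated state that absorbs immediately is visited exactly once
  ch <- buildRawChain(0.5, 0.5, 0, 0, 1)
  expect_equal(expectedVisits(ch, "reactivated", "reactivated"), 1,
               tolerance = 1e-12)
})

test_that("chains that cannot reach niM are rejected", {
  # p3 = 0: the iM state is absorbing, niM unreachable
  ch <- buildRawChain(1, 0, 0.34, 0.33, 0.33)
  expect_error(fundamentalMatrix(ch), "non-absorbing")
  # p4 = 1: the reactivated state is absorbing
  ch2 <- buildRawChain(0.5, 0.5, 1, 0, 0)
  expect_error(expectedAbsorptionTime(ch2, "iM"), "non-absorbing")
})

test_that("absorption bound is certified and reports the spectral surrogate", {
  q <- buildBaselineChain()
  b <- absorptionTimeBound(q)
  N <- fundamentalMatrix(q)
  expect_equal(b$bound, max(rowSums(N)), tolerance = 1e-12)
  expect_gte(b$bound, expectedAbsorptionTime(q, "iM"))
  expect_gte(b$bound, expectedAbsorptionTime(q, "pre_trauma") - 1e-12)
  expect_gt(b$spectralSurrogate, 0)
  # the bound grows without limit as lability traps the reactivated state
  bounds <- vapply(c(0, 0.3, 0.6, 0.9, 0.99, 0.999), function(p4)
    absorptionTimeBound(buildTaskCueChain(taskStrengths = 1,
                                          cueStrength = 0.5,
                                          labilityProb = p4))$bound,
    numeric(1))
  expect_true(all(diff(bounds) > 0))
  expect_gt(bounds[6], 100 * bounds[1])
})

test_that("the bound is non-decreasing in lability over a grid", {
  grid <- seq(0, 0.9, by = 0.1)
  bounds <- vapply(grid, function(p4)
    absorptionTimeBound(buildTaskCueChain(taskStrengths = 1,
                                          cueStrength = 0.5,
                                          labilityProb = p4))$bound,
    numeric(1))
  expect_true(all(diff(bounds) >= 0))
})

test_that("Monte Carlo oracle agrees with the fundamental matrix", {
  q <- buildBaselineChain()
  mc <- monteCarloAbsorption(q, "iM", nTraj = 20000L, seed = 101L)
  expect_lt(abs(mc$meanSteps - 232 / 33), 4 * mc$seSteps)
  expect_lt(abs(mc$meanVisits[["reactivated"]] - 100 / 33),
            4 * mc$seVisits[["reactivated"]])
  expect_lt(abs(mc$meanVisits[["iM"]] - 4), 4 * mc$seVisits[["iM"]])
  expect_identical(mc$truncated, 0L)
})

test_that("Monte Carlo oracle matches analytics on random chains", {
  set.seed(21)
  for (i in 1:5) {
    ch <- randomAbsorbingChain()
    exact <- expectedAbsorptionTime(ch, "iM")
    mc <- monteCarloAbsorption(ch, "iM", nTraj = 5000L, seed = 300L + i)
    expect_lt(abs(mc$meanSteps - exact), 4 * mc$seSteps)
  }
})

test_that("Monte Carlo oracle is deterministic and handles absorbed starts", {
  q <- buildBaselineChain()
  a <- monteCarloAbsorption(q, "iM", nTraj = 500L, seed = 7L)
  b <- monteCarloAbsorption(q, "iM", nTraj = 500L, seed = 7L)
  expect_identical(a, b)
  z <- monteCarloAbsorption(q, "niM", nTraj = 100L, seed = 1L)
  expect_identical(z$meanSteps, 0)
  expect_true(all(z$meanVisits == 0))
})

test_that("expected time in iM plateaus at high task strength", {
  timeIniM <- function(T)
    expectedVisits(buildTaskCueChain(taskStrengths = T, cueStrength = 1,
                                     labilityProb = 0.5), "iM", "iM")
  d5 <- timeIniM(5) - timeIniM(6)
  d15 <- timeIniM(15) - timeIniM(16)
  expect_gt(d5, 0)
  expect_lt(abs(d15), abs(d5))
})
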