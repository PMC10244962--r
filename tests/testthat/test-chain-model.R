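test_that("task reconsolidation probability follows the multiplicative rule", {
  expect_identical(taskReconsolidationProb(0), 1)
  expect_identical(taskReconsolidationProb(1), 0.5)
  expect_identical(taskReconsolidationProb(c(1, 1)), 0.25)
  expect_equal(taskReconsolidationProb(10), 1 / 11)
  # monotone non-increasing in every strength
  grid <- c(0, 0.5, 1, 2, 5, 10, 20)
  vals <- vapply(grid, taskReconsolidationProb, numeric(1))
  expect_true(all(diff(vals) <= 0))
  vals2 <- vapply(grid, function(t) taskReconsolidationProb(c(t, 3)), numeric(1))
  expect_true(all(diff(vals2) <= 0))
  expect_error(taskReconsolidationProb(-1), "non-negative")
  expect_error(taskReconsolidationProb(numeric(0)), "non-negative")
})

test_that("cue reactivation probability is the logistic of cue strength", {
  expect_identical(cueReactivationProb(0), 0.5)
  expect_equal(cueReactivationProb(0.5), 0.6224593312, tolerance = 1e-9)
  expect_equal(cueReactivationProb(1.0), 0.7310585786, tolerance = 1e-9)
  a <- seq(-3, 3, by = 0.5)
  p <- vapply(a, cueReactivationProb, numeric(1))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_error(cueReactivationProb(Inf), "finite")
  expect_error(cueReactivationProb(NA_real_), "finite")
})

test_that("multi-cue models extend the logistic correctly", {
  expect_equal(multiCueProb(0.5, "independent", 5), 0.6224593312^5,
               tolerance = 1e-9)
  expect_equal(multiCueProb(0.5, "nested", 3), 0.657185689277,
               tolerance = 1e-9)
  expect_identical(multiCueProb(0.5, "independent", 1),
                   cueReactivationProb(0.5))
  expect_identical(multiCueProb(0.5, "single", 7), cueReactivationProb(0.5))
  # independent-cue probability strictly decreases with the cue count
  pn <- vapply(1:8, function(n) multiCueProb(0.5, "independent", n),
               numeric(1))
  expect_true(all(diff(pn) < 0))
  expect_error(multiCueProb(0.5, "other", 2), "unknown cue model")
  expect_error(multiCueProb(0.5, "nested", 0), "integer >= 1")
})

test_that("nested cues converge monotonically to the logistic fixed point", {
  # independent oracle: solve x = plogis(x) by bisection
  lo <- 0.5; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (plogis(mid) - mid > 0) lo <- mid else hi <- mid
  }
  fix <- (lo + hi) / 2
  expect_equal(fix, 0.659046068, tolerance = 1e-8)
  pn <- vapply(1:60, function(n) multiCueProb(0.5, "nested", n), numeric(1))
  expect_true(all(diff(abs(pn - fix)) <= 0))  # monotone approach
  expect_equal(pn[60], fix, tolerance = 1e-8)
  # approach from above too
  qn <- vapply(1:60, function(n) multiCueProb(3, "nested", n), numeric(1))
  expect_equal(qn[60], fix, tolerance = 1e-8)
})

test_that("task+cue chain rows match the normalized construction", {
  ch <- buildTaskCueChain(taskStrengths = 0, cueStrength = 0,
                          labilityProb = 0.5)
  expect_equal(unname(transitionMatrix(ch)["reactivated", ]),
               c(0, 0.5, 0.25, 0.25), tolerance = 1e-12)
  ch <- buildTaskCueChain(taskStrengths = 1, cueStrength = 0.5,
                          labilityProb = 0.5)
  expect_equal(unname(transitionMatrix(ch)["reactivated", ]),
               c(0, 1 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(transitionMatrix(ch)["iM", ]),
               c(0, 1 - 0.6224593312, 0.6224593312, 0), tolerance = 1e-9)
  ch2 <- buildTaskCueChain(taskStrengths = c(1, 1), cueStrength = 0.5,
                           labilityProb = 0.5)
  expect_equal(unname(transitionMatrix(ch2)["reactivated", ]),
               c(0, 0.2, 0.4, 0.4), tolerance = 1e-12)
  # strong-task limit: reconsolidation to iM vanishes
  chInf <- buildTaskCueChain(taskStrengths = 1e12, cueStrength = 0.5,
                             labilityProb = 0.5)
  expect_equal(unname(transitionMatrix(chInf)["reactivated", ]),
               c(0, 0, 0.5, 0.5), tolerance = 1e-9)
})

test_that("every constructed chain passes validity over a parameter grid", {
  for (T in c(0, 1, 10)) for (a in c(-2, 0, 1)) for (p4 in c(0, 0.5, 1))
    for (model in c("single", "independent", "nested")) {
      ch <- buildTaskCueChain(taskStrengths = T, cueStrength = a,
                              labilityProb = p4, cueModel = model,
                              cueCount = 3L)
      expect_true(validObject(ch))
      expect_rowStochastic(ch)
    }
})

test_that("chain construction is monotone in task and cue strength", {
  reEntry <- vapply(c(0, 1, 2, 5, 10, 20), function(T)
    transitionProb(buildTaskCueChain(taskStrengths = T), "reactivated", "iM"),
    numeric(1))
  expect_true(all(diff(reEntry) <= 0))
  p3s <- vapply(c(-1, 0, 0.5, 1, 2), function(a)
    transitionProb(buildTaskCueChain(cueStrength = a), "iM", "reactivated"),
    numeric(1))
  expect_true(all(diff(p3s) >= 0))
})

test_that("single-task and degenerate two-task constructions coincide", {
  for (T in c(0, 1, 5, 13)) {
    one <- buildTaskCueChain(taskStrengths = T, cueStrength = 0.5)
    two <- buildTaskCueChain(taskStrengths = c(T, 0), cueStrength = 0.5)
    expect_equal(transitionMatrix(one), transitionMatrix(two),
                 tolerance = 1e-14)
  }
})

test_that("the baseline chain has the fixed published entries", {
  q <- buildBaselineChain()
  M <- transitionMatrix(q)
  expect_equal(unname(M["pre_trauma", ]), c(0, 1, 0, 0))
  expect_equal(unname(M["iM", ]), c(0, 0.5, 0.5, 0))
  expect_equal(unname(M["reactivated", ]), c(0, 0.33, 0.34, 0.33))
  expect_equal(transitionProb(q, "reactivated", "niM"), 0.33)
  expect_rowStochastic(q)
})

test_that("raw chains validate their rows and reject bad probabilities", {
  ch <- buildRawChain(0.964349, 0.035651, 0.035383, 0.959226, 0.005391)
  expect_true(validObject(ch))
  expect_error(buildRawChain(0.5, 0.5, 0.4, 0.7, -0.1), "p6")
  expect_error(buildRawChain(0.5, 0.4, 0.34, 0.33, 0.33), "row iM")
  expect_error(buildRawChain(0.5, 0.5, 0.5, 0.4, 0.3), "row reactivated")
})

test_that("direct matrix construction enforces the chain invariants", {
  M <- transitionMatrix(buildBaselineChain())
  bad <- M; bad["iM", "iM"] <- 0.6
  expect_error(memoryChain(unname(bad)), "sums to")
  bad <- M; bad["niM", ] <- c(0, 0, 0.5, 0.5)
  expect_error(validObject(memoryChain(unname(bad))), "absorbing")
  bad <- M; bad["iM", ] <- c(0.5, 0, 0.5, 0)
  expect_error(validObject(memoryChain(unname(bad))), "never re-entered")
  expect_error(memoryChain(matrix(0.25, 3, 4)), "4x4")
})
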