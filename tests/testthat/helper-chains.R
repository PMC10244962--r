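# draw a random valid absorbing chain with a guaranteed exit to niM, so
# absorption times stay moderate and the Monte Carlo oracle is cheap
randomAbsorbingChain <- function() {
  p3 <- runif(1, 0.1, 0.9)
  w <- rgamma(3, 1)
  row <- w / sum(w)            # (p5, p4, p6)
  # keep at least 5% probability of reconsolidating non-intrusively
  if (row[3] < 0.05) {
    row[1:2] <- row[1:2] * (0.95 / sum(row[1:2]))
    row[3] <- 0.05
  }
  buildRawChain(p2 = 1 - p3, p3 = p3,
                p4 = row[2], p5 = row[1], p6 = row[3])
}

# published group summaries of the four-arm experiment, used throughout
publishedDiaryMeans <- function() {
  list(preMean = 3.334,
       groupMeans = c(no_task_control = 5.111, cue_plus_task = 1.889,
                      task_only = 3.83, cue_only = 4.889))
}

expect_rowStochastic <- function(chain, tol = 1e-12) {
  M <- transitionMatrix(chain)
  expect_true(all(M >= -tol & M <= 1 + tol))
  expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = tol)
}
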