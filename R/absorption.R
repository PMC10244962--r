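.TRANSIENT <- c("pre_trauma", "iM", "reactivated")

# transient 3x3 block; errors unless niM is reachable from every transient
# state (spectral radius of the block < 1)
.transientBlock <- function(chain) {
  M <- transitionMatrix(chain)
  Qt <- M[.TRANSIENT, .TRANSIENT, drop = FALSE]
  rho <- max(Mod(eigen(Qt, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12)
    .stopf(paste("non-absorbing chain: niM is unreachable from some transient",
                 "state (spectral radius of the transient block is %.12g)"),
           rho)
  Qt
}

#' Fundamental matrix of the memory chain
#'
#' Computes `N = (I - Q_t)^-1` over the transient states
#' (pre_trauma, iM, reactivated), where `Q_t` is the transient block of the
#' transition matrix. Entry `N[i, j]` is the expected number of visits to
#' transient state `j`, counting the start, before absorption into `niM`
#' when starting from `i`.
#'
#' @param chain a [MemoryChain-class] whose absorbing `niM` state is
#'   reachable from every transient state.
#' @return 3x3 numeric matrix with state dimnames.
#' @export
#' @examples
#' fundamentalMatrix(buildBaselineChain())
setGeneric("fundamentalMatrix", function(chain) standardGeneric("fundamentalMatrix"))

#' @rdname fundamentalMatrix
#' @export
setMethod("fundamentalMatrix", "MemoryChain", function(chain) {
  Qt <- .transientBlock(chain)
  N <- solve(diag(3) - Qt)
  dimnames(N) <- list(.TRANSIENT, .TRANSIENT)
  N
})

#' Expected number of steps before absorption into niM
#'
#' Row sum of the fundamental matrix for the start state: the expected
#' number of steps a memory spends in transient states (counting the start)
#' before it settles as a non-intrusive memory. Starting from `niM` the
#' time is 0 by convention.
#'
#' @param chain a [MemoryChain-class].
#' @param start state label to start from.
#' @return expected steps (non-negative real).
#' @export
#' @examples
#' expectedAbsorptionTime(buildBaselineChain(), "iM")
setGeneric("expectedAbsorptionTime",
           function(chain, start = "iM") standardGeneric("expectedAbsorptionTime"))

#' @rdname expectedAbsorptionTime
#' @export
setMethod("expectedAbsorptionTime", "MemoryChain", function(chain, start = "iM") {
  start <- match.arg(start, .STATES)
  if (start == "niM") return(0)
  sum(fundamentalMatrix(chain)[start, ])
})

#' Expected visits to a transient state before absorption
#'
#' The (start, target) entry of the fundamental matrix: the expected number
#' of times the chain occupies `target` (counting the start if
#' `start == target`) before absorption into `niM`.
#'
#' @param chain a [MemoryChain-class].
#' @param start,target transient state labels.
#' @return expected visit count (non-negative real).
#' @export
#' @examples
#' expectedVisits(buildBaselineChain(), "iM", "reactivated")
setGeneric("expectedVisits",
           function(chain, start = "iM", target = "reactivated")
             standardGeneric("expectedVisits"))

#' @rdname expectedVisits
#' @export
setMethod("expectedVisits", "MemoryChain",
          function(chain, start = "iM", target = "reactivated") {
  start <- match.arg(start, .TRANSIENT)
  target <- match.arg(target, .TRANSIENT)
  fundamentalMatrix(chain)[start, target]
})

#' Full absorption summary
#'
#' Bundles the fundamental matrix, the per-start expected absorption times
#' (its row sums) and the expected visits to the reactivated state (its
#' reactivated column) into an [AbsorptionSummary-class].
#'
#' @param chain a [MemoryChain-class].
#' @return an [AbsorptionSummary-class].
#' @export
#' @examples
#' absorptionSummary(buildBaselineChain())
setGeneric("absorptionSummary", function(chain) standardGeneric("absorptionSummary"))

#' @rdname absorptionSummary
#' @export
setMethod("absorptionSummary", "MemoryChain", function(chain) {
  N <- fundamentalMatrix(chain)
  new("AbsorptionSummary", fundamental = N,
      timeToAbsorption = rowSums(N),
      visitsToReactivated = N[, "reactivated"])
})

#' Upper bound on the expected absorption time
#'
#' Reports a certified upper bound over all transient starting states — the
#' maximum row sum of the fundamental matrix, which is exact for the worst
#' start — together with the spectral surrogate `1/(1 - |lambda2|)`, the
#' geometric-decay timescale implied by the second-largest eigenvalue
#' modulus. The bound diverges as the reactivated state approaches an
#' absorbing state of its own (lability probability near 1 with no exit to
#' niM).
#'
#' @param chain a [MemoryChain-class].
#' @return list with elements `bound` (max-row-sum, exact worst-case
#'   expected time) and `spectralSurrogate`.
#' @export
#' @examples
#' absorptionTimeBound(buildBaselineChain())
setGeneric("absorptionTimeBound", function(chain) standardGeneric("absorptionTimeBound"))

#' @rdname absorptionTimeBound
#' @export
setMethod("absorptionTimeBound", "MemoryChain", function(chain) {
  N <- fundamentalMatrix(chain)
  l2 <- spectralDecompose(chain)@secondModulus
  list(bound = max(rowSums(N)),
       spectralSurrogate = if (l2 < 1) 1 / (1 - l2) else Inf)
})

#' Monte Carlo estimate of absorption time and state visits
#'
#' Simulates trajectories of the chain from `start` until absorption into
#' `niM` (or a step cap) and returns the mean number of steps, mean visits
#' per transient state, and their standard errors. This is the independent
#' stochastic oracle for the analytic fundamental-matrix quantities; it is
#' reproducible given `seed`.
#'
#' @param chain a [MemoryChain-class].
#' @param start state label to start trajectories from.
#' @param nTraj number of trajectories (>= 1).
#' @param seed integer seed.
#' @param maxSteps cap on steps per trajectory; trajectories still
#'   unabsorbed at the cap are counted in `truncated`.
#' @return list with `meanSteps`, `seSteps`, `meanVisits`, `seVisits`
#'   (named over transient states), `nTraj` and `truncated`.
#' @export
#' @examples
#' monteCarloAbsorption(buildBaselineChain(), "iM", nTraj = 1000, seed = 1)
setGeneric("monteCarloAbsorption",
           function(chain, start = "iM", nTraj = 10000L, seed = 1L,
                    maxSteps = 1e6) standardGeneric("monteCarloAbsorption"))

#' @rdname monteCarloAbsorption
#' @export
setMethod("monteCarloAbsorption", "MemoryChain",
          function(chain, start = "iM", nTraj = 10000L, seed = 1L,
                   maxSteps = 1e6) {
  start <- match.arg(start, .STATES)
  if (!is.numeric(nTraj) || nTraj < 1) .stopf("nTraj must be >= 1")
  nTraj <- as.integer(nTraj)
  set.seed(as.integer(seed))
  M <- transitionMatrix(chain)
  cumP <- t(apply(M, 1, cumsum))
  steps <- numeric(nTraj)
  visits <- matrix(0, nTraj, 3, dimnames = list(NULL, .TRANSIENT))
  truncated <- 0L
  if (start == "niM") {
    se <- c(pre_trauma = 0, iM = 0, reactivated = 0)
    return(list(meanSteps = 0, seSteps = 0, meanVisits = se, seVisits = se,
                nTraj = nTraj, truncated = 0L))
  }
  cur <- rep.int(match(start, .STATES), nTraj)
  alive <- seq_len(nTraj)
  visits[cbind(alive, cur[alive])] <- 1
  nstep <- 0
  while (length(alive)) {
    nstep <- nstep + 1
    if (nstep > maxSteps) { truncated <- length(alive); break }
    u <- stats::runif(length(alive))
    c1 <- cumP[cur[alive], , drop = FALSE]
    nxt <- 1L + (u > c1[, 1]) + (u > c1[, 2]) + (u > c1[, 3])
    steps[alive] <- steps[alive] + 1
    cur[alive] <- nxt
    tr <- nxt != 4L
    if (any(tr)) {
      idx <- alive[tr]
      visits[cbind(idx, nxt[tr])] <- visits[cbind(idx, nxt[tr])] + 1
    }
    alive <- alive[tr]
  }
  sdv <- apply(visits, 2, stats::sd)
  list(meanSteps = mean(steps),
       seSteps = stats::sd(steps) / sqrt(nTraj),
       meanVisits = colMeans(visits),
       seVisits = sdv / sqrt(nTraj),
       nTraj = nTraj, truncated = truncated)
})
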