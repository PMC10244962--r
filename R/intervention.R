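#' Construct a dose schedule
#'
#' Builds a [DoseSchedule-class] from a list of segments, each a list with
#' integer `from`, `to` and a `chain`. Segments must start at step 1, be
#' consecutive, and cover the horizon exactly.
#'
#' @param segments list of segment lists.
#' @param horizon total number of steps; defaults to the last segment's
#'   `to`.
#' @return a [DoseSchedule-class].
#' @export
#' @examples
#' q <- buildBaselineChain()
#' doseSchedule(list(list(from = 1, to = 5, chain = q)))
doseSchedule <- function(segments, horizon = NULL) {
  if (!is.list(segments) || !length(segments))
    .stopf("a schedule needs at least one segment")
  if (is.null(horizon))
    horizon <- max(vapply(segments, function(s) as.integer(s$to), integer(1)))
  segments <- lapply(segments, function(s)
    list(from = as.integer(s$from), to = as.integer(s$to), chain = s$chain))
  segments <- segments[order(vapply(segments, `[[`, integer(1), "from"))]
  new("DoseSchedule", segments = segments, horizon = as.integer(horizon))
}

#' Single-dose treatment schedule
#'
#' A schedule delivering the task intervention in the first time step only:
#' step 1 uses the task-plus-cue chain; the remaining steps use its no-task
#' counterpart (same cue strength, cue model and lability probability,
#' task strength 0). For users who read the no-treatment comparator as the
#' fixed baseline matrix instead, `rest = "baseline"` switches the later
#' segment to [buildBaselineChain()].
#'
#' @inheritParams interventionParams
#' @param horizon total steps (>= 1).
#' @param rest chain governing steps 2..horizon: `"no_task"` (default) or
#'   `"baseline"`.
#' @return a [DoseSchedule-class].
#' @export
#' @examples
#' singleDoseSchedule(taskStrengths = 5, horizon = 10)
singleDoseSchedule <- function(taskStrengths, cueStrength = 0.5,
                               labilityProb = 0.5, horizon = 20L,
                               cueModel = c("single", "independent", "nested"),
                               cueCount = 1L,
                               rest = c("no_task", "baseline")) {
  cueModel <- match.arg(cueModel)
  rest <- match.arg(rest)
  if (!is.numeric(horizon) || horizon < 1) .stopf("horizon must be >= 1")
  horizon <- as.integer(horizon)
  dosed <- buildTaskCueChain(taskStrengths = taskStrengths,
                             cueStrength = cueStrength,
                             labilityProb = labilityProb,
                             cueModel = cueModel, cueCount = cueCount)
  if (horizon == 1L)
    return(doseSchedule(list(list(from = 1L, to = 1L, chain = dosed))))
  after <- if (rest == "baseline") buildBaselineChain() else
    buildTaskCueChain(taskStrengths = 0, cueStrength = cueStrength,
                      labilityProb = labilityProb, cueModel = cueModel,
                      cueCount = cueCount)
  doseSchedule(list(list(from = 1L, to = 1L, chain = dosed),
                    list(from = 2L, to = horizon, chain = after)))
}

#' Evolve a state distribution through a schedule
#'
#' Propagates the memory-state distribution analytically through the
#' time-inhomogeneous schedule: at each step the row vector is multiplied
#' by that step's transition matrix. Mass in the absorbing `niM` state is
#' non-decreasing along the trajectory and every row sums to 1.
#'
#' @param schedule a [DoseSchedule-class], or a single [MemoryChain-class]
#'   (applied at every step up to `horizon`).
#' @param initial a [StateDistribution-class] or a 4-vector of
#'   probabilities; defaults to the canonical start with memories split
#'   evenly between the intrusive and reactivated states.
#' @param horizon required when `schedule` is a single chain.
#' @return numeric matrix with `horizon + 1` rows (steps `0..horizon` as
#'   rownames) and the four states as columns.
#' @export
#' @examples
#' evolve(buildBaselineChain(), horizon = 5)
setGeneric("evolve", function(schedule, initial = NULL, horizon = NULL)
  standardGeneric("evolve"))

.initialProbs <- function(initial) {
  if (is.null(initial)) initial <- stateDistribution(c(0, 0.5, 0.5, 0))
  if (is.numeric(initial)) initial <- stateDistribution(initial)
  stopifnot(is(initial, "StateDistribution"))
  validObject(initial)
  stateProbs(initial)
}

#' @rdname evolve
#' @export
setMethod("evolve", "DoseSchedule", function(schedule, initial = NULL,
                                             horizon = NULL) {
  validObject(schedule)
  pi0 <- .initialProbs(initial)
  H <- schedule@horizon
  traj <- matrix(NA_real_, H + 1L, 4L,
                 dimnames = list(0:H, .STATES))
  traj[1L, ] <- pi0
  cur <- pi0
  for (s in schedule@segments) {
    M <- transitionMatrix(s$chain)
    for (step in s$from:s$to) {
      cur <- as.numeric(cur %*% M)
      traj[step + 1L, ] <- cur
    }
  }
  traj
})

#' @rdname evolve
#' @export
setMethod("evolve", "MemoryChain", function(schedule, initial = NULL,
                                            horizon = NULL) {
  if (is.null(horizon)) .stopf("horizon is required when evolving a single chain")
  sched <- doseSchedule(list(list(from = 1L, to = as.integer(horizon),
                                  chain = schedule)))
  evolve(sched, initial)
})

#' Intrusive-memory probability curves from a trajectory
#'
#' Extracts, per step, both readings of "probability of intrusive
#' memories": the consolidated intrusive state alone (`p_iM`) and the
#' intrusive plus reactivated states (`p_intrusive`). Both are emitted
#' because either aggregation is defensible; qualitative orderings agree.
#'
#' @param trajectory matrix returned by [evolve()].
#' @return data.frame with columns `step`, `p_iM`, `p_intrusive`.
#' @export
#' @examples
#' imProbabilityCurve(evolve(buildBaselineChain(), horizon = 5))
imProbabilityCurve <- function(trajectory) {
  if (!is.matrix(trajectory) || !nrow(trajectory) ||
      !all(.STATES %in% colnames(trajectory)))
    .stopf("trajectory must be a non-empty matrix with the four state columns")
  data.frame(step = as.integer(rownames(trajectory)),
             p_iM = as.numeric(trajectory[, "iM"]),
             p_intrusive = as.numeric(trajectory[, "iM"] +
                                        trajectory[, "reactivated"]))
}

#' Paired task / no-task trajectories under a multi-cue scenario
#'
#' Builds two constant chains whose iM-to-reactivated entry comes from the
#' configured multi-cue model — one with the given task strengths, one with
#' no task — and evolves both from the same initial distribution. Used to
#' compare treatment against its absence under single, independent or
#' nested reminder cues.
#'
#' @inheritParams interventionParams
#' @param n cue count (independent) or nesting depth (nested).
#' @param horizon steps to simulate.
#' @param initial initial distribution (default: even iM/reactivated split).
#' @return list with matrices `task` and `no_task`.
#' @export
#' @examples
#' tr <- cueScenario(taskStrengths = 1, cueModel = "independent", n = 5)
#' tail(tr$task)
cueScenario <- function(taskStrengths, cueModel = c("single", "independent",
                                                    "nested"),
                        n = 1L, cueStrength = 0.5, labilityProb = 0.5,
                        horizon = 20L, initial = NULL) {
  cueModel <- match.arg(cueModel)
  mk <- function(ts) buildTaskCueChain(taskStrengths = ts,
                                       cueStrength = cueStrength,
                                       labilityProb = labilityProb,
                                       cueModel = cueModel, cueCount = n)
  list(task = evolve(mk(taskStrengths), initial, horizon = horizon),
       no_task = evolve(mk(0), initial, horizon = horizon))
}

#' Sample a single trajectory through a schedule
#'
#' Seeded stochastic counterpart of [evolve()]: samples one state path
#' through the (possibly time-inhomogeneous) schedule. Intended for
#' visualization and as an oracle cross-check of the analytic propagation.
#'
#' @param schedule a [DoseSchedule-class].
#' @param start state label to start from.
#' @param seed integer seed.
#' @return character vector of `horizon + 1` visited state labels.
#' @export
#' @examples
#' q <- buildBaselineChain()
#' sampleTrajectory(doseSchedule(list(list(from = 1, to = 10, chain = q))),
#'                  seed = 7)
sampleTrajectory <- function(schedule, start = "iM", seed = 1L) {
  stopifnot(is(schedule, "DoseSchedule"))
  validObject(schedule)
  start <- match.arg(start, .STATES)
  set.seed(as.integer(seed))
  path <- character(schedule@horizon + 1L)
  cur <- match(start, .STATES)
  path[1L] <- .STATES[cur]
  i <- 2L
  for (s in schedule@segments) {
    M <- transitionMatrix(s$chain)
    for (step in s$from:s$to) {
      cur <- sample.int(4L, 1L, prob = M[cur, ])
      path[i] <- .STATES[cur]
      i <- i + 1L
    }
  }
  path
}
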