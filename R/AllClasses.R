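#' @import methods
NULL

# canonical state order: memories consolidate out of pre_trauma immediately,
# cycle between the consolidated intrusive (iM) and reactivated states, and
# absorb into the non-intrusive (niM) state
.STATES <- c("pre_trauma", "iM", "reactivated", "niM")

#' Memory-state labels
#'
#' The fixed, ordered labels of the four memory states: `pre_trauma` (trauma
#' experienced, memory not yet consolidated), `iM` (consolidated intrusive
#' memory), `reactivated` (memory rendered labile by a reminder cue) and
#' `niM` (non-intrusive memory, the absorbing state).
#'
#' @return character vector of length 4.
#' @export
#' @examples
#' memoryStates()
memoryStates <- function() .STATES

#' MemoryChain: a four-state intrusive-memory transition matrix
#'
#' S4 container for the row-stochastic transition matrix of the four-state
#' memory chain. Rows index the current state, columns the next state;
#' distributions are row vectors updated by right-multiplication. Validity
#' enforces row-stochasticity, the deterministic consolidation row
#' (`pre_trauma` goes to `iM` with probability 1), the absorbing `niM` row,
#' and that `pre_trauma` is never re-entered.
#'
#' @slot transitionMatrix 4x4 numeric matrix with state dimnames.
#' @slot params list; provenance of the construction (task strengths, cue
#'   strength, lability probability, cue model), possibly empty.
#'
#' @seealso [memoryChain()], [buildTaskCueChain()], [buildBaselineChain()],
#'   [buildRawChain()]
#' @export
setClass("MemoryChain",
  representation(transitionMatrix = "matrix", params = "list"),
  prototype(params = list())
)

.validMemoryChain <- function(object) {
  M <- object@transitionMatrix
  tol <- 1e-9
  msg <- character()
  if (!is.numeric(M) || !identical(dim(M), c(4L, 4L)))
    return("transitionMatrix must be a numeric 4x4 matrix")
  if (!identical(rownames(M), .STATES) || !identical(colnames(M), .STATES))
    msg <- c(msg, sprintf("dimnames must both be (%s)",
                          paste(.STATES, collapse = ", ")))
  if (anyNA(M) || any(M < -tol) || any(M > 1 + tol))
    msg <- c(msg, "all transition probabilities must lie in [0, 1]")
  rs <- rowSums(M)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    msg <- c(msg, sprintf("row '%s' sums to %.12g, not 1",
                          .STATES[bad[1]], rs[bad[1]]))
  if (max(abs(M[1, ] - c(0, 1, 0, 0))) > tol)
    msg <- c(msg, "row pre_trauma must be (0, 1, 0, 0): consolidation is certain")
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > tol)
    msg <- c(msg, "row niM must be (0, 0, 0, 1): niM is absorbing")
  if (max(abs(M[2:4, 1])) > tol)
    msg <- c(msg, "column pre_trauma must be zero below the diagonal: the pre-trauma state is never re-entered")
  if (length(msg)) msg else TRUE
}
setValidity("MemoryChain", .validMemoryChain)

#' InterventionParams: interpretable intervention parameters
#'
#' Parameters of the task-plus-cue construction of a [MemoryChain-class]:
#' one or more task strengths acting multiplicatively on reconsolidation,
#' the reminder-cue strength entering the logistic reactivation function,
#' the lability probability (chance a reactivated memory stays reactivated),
#' and the multi-cue model.
#'
#' @slot taskStrengths numeric, all >= 0; task strength(s) T (T1, T2, ...).
#' @slot cueStrength numeric scalar; reminder-cue strength alpha.
#' @slot labilityProb numeric in \[0, 1\]; probability p4 that a reactivated
#'   memory remains reactivated.
#' @slot cueModel one of `"single"`, `"independent"`, `"nested"`.
#' @slot cueCount integer >= 1; number of independent cues or nesting depth.
#'
#' @seealso [interventionParams()], [buildTaskCueChain()]
#' @export
setClass("InterventionParams",
  representation(taskStrengths = "numeric", cueStrength = "numeric",
                 labilityProb = "numeric", cueModel = "character",
                 cueCount = "integer")
)

setValidity("InterventionParams", function(object) {
  msg <- character()
  if (!length(object@taskStrengths) || anyNA(object@taskStrengths) ||
      any(object@taskStrengths < 0))
    msg <- c(msg, "taskStrengths must be non-negative and non-missing")
  if (length(object@cueStrength) != 1L || !is.finite(object@cueStrength))
    msg <- c(msg, "cueStrength must be a single finite number")
  if (length(object@labilityProb) != 1L || is.na(object@labilityProb) ||
      object@labilityProb < 0 || object@labilityProb > 1)
    msg <- c(msg, "labilityProb must be a single probability in [0, 1]")
  if (length(object@cueModel) != 1L ||
      !object@cueModel %in% c("single", "independent", "nested"))
    msg <- c(msg, "cueModel must be one of 'single', 'independent', 'nested'")
  if (length(object@cueCount) != 1L || is.na(object@cueCount) ||
      object@cueCount < 1L)
    msg <- c(msg, "cueCount must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' SpectralSummary: eigenstructure of a memory chain
#'
#' Result of [spectralDecompose()]: eigenvalues sorted by modulus
#' (descending), the right-eigenvector matrix, the second-largest eigenvalue
#' modulus and the relaxation time derived from it, plus a flag recording
#' whether the eigenvector basis was well conditioned (when it is not,
#' matrix powers fall back to direct multiplication).
#'
#' @slot eigenvalues complex vector of length 4, modulus-descending.
#' @slot vectors 4x4 complex matrix of right eigenvectors (columns).
#' @slot secondModulus numeric; |lambda_2|.
#' @slot relaxationTime numeric; -1/log|lambda_2| (steps), Inf if
#'   |lambda_2| = 1, 0 if |lambda_2| = 0.
#' @slot diagonalizable logical; FALSE when the eigenbasis is too
#'   ill-conditioned to reconstruct powers reliably.
#' @export
setClass("SpectralSummary",
  representation(eigenvalues = "complex", vectors = "matrix",
                 secondModulus = "numeric", relaxationTime = "numeric",
                 diagonalizable = "logical")
)

#' AbsorptionSummary: fundamental-matrix persistence summary
#'
#' Result of [absorptionSummary()]: the fundamental matrix
#' N = (I - Q_t)^-1 over the three transient states, whose (i, j) entry is
#' the expected number of visits to transient state j starting from i before
#' absorption into `niM`; the per-start expected absorption times (row sums
#' of N); and the expected visits to the reactivated state (its column).
#'
#' @slot fundamental 3x3 numeric matrix over
#'   (pre_trauma, iM, reactivated).
#' @slot timeToAbsorption named numeric of length 3; expected steps to
#'   absorption per transient start state.
#' @slot visitsToReactivated named numeric of length 3; expected visits to
#'   the reactivated state per transient start state.
#' @export
setClass("AbsorptionSummary",
  representation(fundamental = "matrix", timeToAbsorption = "numeric",
                 visitsToReactivated = "numeric")
)

#' StateDistribution: memory-state probabilities at a time step
#'
#' A probability vector over the four memory states together with the time
#' step at which it holds.
#'
#' @slot probs named numeric of length 4 summing to 1.
#' @slot step non-negative integer time step.
#' @seealso [stateDistribution()]
#' @export
setClass("StateDistribution",
  representation(probs = "numeric", step = "integer")
)

setValidity("StateDistribution", function(object) {
  p <- object@probs
  msg <- character()
  if (length(p) != 4L || !identical(names(p), .STATES))
    msg <- c(msg, "probs must be length 4 and named by the memory states")
  else {
    if (anyNA(p) || any(p < -1e-12) || any(p > 1 + 1e-12))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-12)
      msg <- c(msg, sprintf("probabilities sum to %.15g, not 1", sum(p)))
  }
  if (length(object@step) != 1L || is.na(object@step) || object@step < 0L)
    msg <- c(msg, "step must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' DoseSchedule: a time-inhomogeneous treatment schedule
#'
#' An ordered list of step segments, each governed by its own
#' [MemoryChain-class], covering steps 1..horizon consecutively without gaps
#' or overlap. Applied by [evolve()].
#'
#' @slot segments list; each element a list with integer `from`, `to` and a
#'   `chain` (a [MemoryChain-class]).
#' @slot horizon integer; total number of steps.
#' @seealso [doseSchedule()], [singleDoseSchedule()], [evolve()]
#' @export
setClass("DoseSchedule",
  representation(segments = "list", horizon = "integer")
)

setValidity("DoseSchedule", function(object) {
  segs <- object@segments
  if (!length(segs)) return("schedule must contain at least one segment")
  for (s in segs) {
    if (!is.list(s) || !all(c("from", "to", "chain") %in% names(s)))
      return("each segment needs 'from', 'to' and 'chain'")
    if (!is(s$chain, "MemoryChain")) return("segment 'chain' must be a MemoryChain")
  }
  from <- vapply(segs, function(s) as.integer(s$from), integer(1))
  to   <- vapply(segs, function(s) as.integer(s$to), integer(1))
  if (any(to < from)) return("segment 'to' must be >= 'from'")
  o <- order(from)
  from <- from[o]; to <- to[o]
  if (from[1] != 1L)
    return("segments must start at step 1")
  if (length(from) > 1L && any(from[-1] != to[-length(to)] + 1L))
    return("segments must be consecutive: gaps or overlaps found")
  if (to[length(to)] != object@horizon)
    return(sprintf("segments cover steps 1..%d but horizon is %d",
                   to[length(to)], object@horizon))
  TRUE
})

#' DiarySummary: intrusion-diary group summaries
#'
#' Per-group summaries of intrusion-diary counts from the four-arm
#' reminder-cue/task design: the pooled pre-intervention 24 h mean, and the
#' one-week means (with optional standard errors and group sizes) for the
#' arms `no_task_control`, `cue_plus_task`, `task_only` and `cue_only`.
#' Feeds [estimateTransitions()].
#'
#' @slot preMean numeric; pooled mean intrusion count in the 24 h
#'   post-trauma window.
#' @slot preSE numeric; its standard error (NA if unknown).
#' @slot groupMeans named numeric; one-week mean counts per arm.
#' @slot groupSE named numeric; standard errors (NA where unknown).
#' @slot groupN named numeric; participants per arm (NA where unknown).
#' @seealso [diarySummary()], [summarizeDiaries()]
#' @export
setClass("DiarySummary",
  representation(preMean = "numeric", preSE = "numeric",
                 groupMeans = "numeric", groupSE = "numeric",
                 groupN = "numeric")
)

.DIARY_GROUPS <- c("no_task_control", "cue_plus_task", "task_only", "cue_only")

setValidity("DiarySummary", function(object) {
  msg <- character()
  if (length(object@preMean) != 1L || is.na(object@preMean) ||
      object@preMean < 0)
    msg <- c(msg, "preMean must be a single non-negative number")
  if (!all(.DIARY_GROUPS %in% names(object@groupMeans)))
    msg <- c(msg, sprintf("groupMeans must be named with the four arms: %s",
                          paste(.DIARY_GROUPS, collapse = ", ")))
  else if (any(object@groupMeans < 0, na.rm = TRUE))
    msg <- c(msg, "groupMeans must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TransitionEstimates: empirically estimated transition probabilities
#'
#' The five unknown transition probabilities of the memory chain estimated
#' from intrusion-diary summaries under the Poisson assumption, kept at full
#' precision, together with the intermediate Poisson zero-probabilities per
#' group. Rounded half-up to 3 decimals only at presentation.
#'
#' @slot p2,p3,p4,p5,p6 numeric transition probabilities
#'   (p2 + p3 = 1, p4 + p5 + p6 = 1).
#' @slot intermediates list of the per-group zero-probabilities and their
#'   complements used in the estimation.
#' @seealso [estimateTransitions()], [buildEmpiricalChain()]
#' @export
setClass("TransitionEstimates",
  representation(p2 = "numeric", p3 = "numeric", p4 = "numeric",
                 p5 = "numeric", p6 = "numeric", intermediates = "list")
)

setValidity("TransitionEstimates", function(object) {
  p <- c(p2 = object@p2, p3 = object@p3, p4 = object@p4,
         p5 = object@p5, p6 = object@p6)
  msg <- character()
  if (anyNA(p) || any(p < -1e-12) || any(p > 1 + 1e-12))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (abs(object@p2 + object@p3 - 1) > 1e-9)
    msg <- c(msg, "p2 + p3 must equal 1")
  if (abs(object@p4 + object@p5 + object@p6 - 1) > 1e-9)
    msg <- c(msg, "p4 + p5 + p6 must equal 1")
  if (length(msg)) msg else TRUE
})

#' DiaryDataset: per-participant synthetic intrusion diaries
#'
#' Per-participant intrusion counts for the four experimental arms over the
#' pre-intervention 24 h window (`pre24h`) and the subsequent week (`week`),
#' together with the generating Poisson means and the seed used.
#'
#' @slot records data.frame with columns `participant_id`, `group`,
#'   `period`, `count`.
#' @slot generatingMeans list with elements `preMean` and `groupMeans`.
#' @slot seed integer seed used for generation (NA if not generated here).
#' @seealso [generateDiaries()], [summarizeDiaries()]
#' @export
setClass("DiaryDataset",
  representation(records = "data.frame", generatingMeans = "list",
                 seed = "integer")
)

setValidity("DiaryDataset", function(object) {
  rec <- object@records
  need <- c("participant_id", "group", "period", "count")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(rec)) {
    if (any(!rec$period %in% c("pre24h", "week")))
      return("period must be 'pre24h' or 'week'")
    if (any(!rec$group %in% .DIARY_GROUPS))
      return("group must be one of the four experimental arms")
    cnt <- rec$count
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
      return("counts must be non-negative integers")
  }
  TRUE
})

#' LHSDesign: a Latin-hypercube parameter design
#'
#' A stratified (one sample per equal-width stratum, per parameter) design
#' over named parameter ranges, as produced by [lhsSample()].
#'
#' @slot samples n x k numeric matrix, columns named by parameter.
#' @slot ranges named list of c(low, high) per parameter.
#' @slot seed integer seed used.
#' @export
setClass("LHSDesign",
  representation(samples = "matrix", ranges = "list", seed = "integer")
)

setValidity("LHSDesign", function(object) {
  X <- object@samples
  rg <- object@ranges
  if (!is.numeric(X) || is.null(colnames(X)))
    return("samples must be a numeric matrix with parameter column names")
  if (!identical(colnames(X), names(rg)))
    return("column names of samples must match names of ranges")
  n <- nrow(X)
  for (j in colnames(X)) {
    lo <- rg[[j]][1]; hi <- rg[[j]][2]
    if (any(X[, j] < lo - 1e-12) || any(X[, j] > hi + 1e-12))
      return(sprintf("samples for '%s' fall outside [%g, %g]", j, lo, hi))
    stratum <- floor((X[, j] - lo) / (hi - lo) * n)
    stratum[stratum == n] <- n - 1L
    if (!setequal(stratum, 0:(n - 1)))
      return(sprintf("parameter '%s' violates one-sample-per-stratum", j))
  }
  TRUE
})
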