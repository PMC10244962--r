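#' Poisson probability of zero events
#'
#' Probability of observing no intrusive memories over a recording period
#' when intrusion counts are Poisson with the given mean: `exp(-mean)`.
#'
#' @param mean non-negative Poisson mean.
#' @return a probability.
#' @export
#' @examples
#' poissonZero(1.889)
poissonZero <- function(mean) {
  if (!is.numeric(mean) || anyNA(mean) || any(mean < 0))
    .stopf("the Poisson mean must be non-negative")
  exp(-mean)
}

#' Construct a diary summary
#'
#' Bundles the pooled pre-intervention 24 h mean intrusion count and the
#' one-week group means for the four experimental arms into a
#' [DiarySummary-class]. Standard errors and group sizes are optional.
#'
#' @param preMean pooled pre-intervention mean count.
#' @param groupMeans named numeric with entries `no_task_control`,
#'   `cue_plus_task`, `task_only`, `cue_only`.
#' @param preSE,groupSE,groupN optional standard errors / sizes.
#' @return a [DiarySummary-class].
#' @export
#' @examples
#' diarySummary(3.334, c(no_task_control = 5.111, cue_plus_task = 1.889,
#'                       task_only = 3.83, cue_only = 4.889))
diarySummary <- function(preMean, groupMeans, preSE = NA_real_,
                         groupSE = NULL, groupN = NULL) {
  groupMeans <- unlist(groupMeans)
  if (is.null(groupSE))
    groupSE <- stats::setNames(rep(NA_real_, length(.DIARY_GROUPS)), .DIARY_GROUPS)
  if (is.null(groupN))
    groupN <- stats::setNames(rep(NA_real_, length(.DIARY_GROUPS)), .DIARY_GROUPS)
  new("DiarySummary", preMean = as.numeric(preMean),
      preSE = as.numeric(preSE),
      groupMeans = groupMeans[.DIARY_GROUPS],
      groupSE = unlist(groupSE)[.DIARY_GROUPS],
      groupN = unlist(groupN)[.DIARY_GROUPS])
}

#' Group mean intrusion counts from the four-arm reminder-cue/task study
#'
#' The published summary statistics of the four-arm experiment (no-task
#' control, reminder cue plus task, task only, reminder cue only): the
#' pooled mean intrusion count in the 24 h after trauma exposure and the
#' per-arm means over the following week, with standard errors. These are
#' the inputs of the empirical parametrization worked example.
#'
#' @return a [DiarySummary-class].
#' @export
#' @examples
#' estimateTransitions(intrusionDiaryMeans())
intrusionDiaryMeans <- function() {
  diarySummary(
    preMean = 3.334, preSE = 0.268,
    groupMeans = c(no_task_control = 5.111, cue_plus_task = 1.889,
                   task_only = 3.83, cue_only = 4.889),
    groupSE = c(no_task_control = 0.996, cue_plus_task = 0.411,
                task_only = 0.682, cue_only = 0.828))
}

#' Estimate transition probabilities from diary summaries
#'
#' The Poisson procedure for parametrizing the memory chain from intrusion
#' diaries. With intrusion counts Poisson, the pre-intervention 24 h window
#' identifies the iM row: an intrusion means the memory reconsolidated
#' intrusively, so `p2 = 1 - exp(-preMean)` and the reactivation
#' probability is its complement `p3 = exp(-preMean)`. The cue-only arm's
#' week then identifies lability jointly with reactivation, giving the
#' marginal `p4 = p3 * (1 - exp(-mean_cue_only))`; the cue-plus-task arm
#' identifies successful non-intrusive reconsolidation,
#' `p6 = p3 * exp(-mean_cue_plus_task)`; and `p5 = 1 - p4 - p6`. The
#' no-task-control and task-only means do not enter the estimator (they
#' serve as checks and for synthetic-data recovery studies). All
#' intermediates are kept at full precision; rounding is presentation-only.
#'
#' @param summary a [DiarySummary-class] (see [diarySummary()]).
#' @return a [TransitionEstimates-class].
#' @export
#' @examples
#' estimateTransitions(intrusionDiaryMeans())
estimateTransitions <- function(summary) {
  stopifnot(is(summary, "DiarySummary"))
  validObject(summary)
  if (summary@preMean <= 0)
    .stopf("the pre-intervention mean must be positive to identify p2 and p3")
  mCue <- summary@groupMeans[["cue_only"]]
  mCueTask <- summary@groupMeans[["cue_plus_task"]]
  if (is.na(mCue) || is.na(mCueTask))
    .stopf("cue_only and cue_plus_task means are required")
  p3 <- poissonZero(summary@preMean)
  p2 <- 1 - p3
  zeroCueOnly <- poissonZero(mCue)
  zeroCueTask <- poissonZero(mCueTask)
  p4 <- p3 * (1 - zeroCueOnly)
  p6 <- p3 * zeroCueTask
  if (p4 + p6 > 1)
    .stopf("inconsistent estimates: p4 + p6 = %.6f > 1", p4 + p6)
  p5 <- 1 - p4 - p6
  new("TransitionEstimates", p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6,
      intermediates = list(
        zeroCueOnly = zeroCueOnly,
        anyCueOnly = 1 - zeroCueOnly,
        zeroCuePlusTask = zeroCueTask,
        preMean = summary@preMean,
        cueOnlyMean = mCue,
        cuePlusTaskMean = mCueTask))
}

#' Transition estimates as a named vector
#'
#' @param estimates a [TransitionEstimates-class].
#' @param digits if non-NULL, round half-up to this many decimals
#'   (presentation only).
#' @return named numeric (p2, p3, p4, p5, p6).
#' @export
#' @examples
#' transitionProbs(estimateTransitions(intrusionDiaryMeans()), digits = 3)
transitionProbs <- function(estimates, digits = NULL) {
  stopifnot(is(estimates, "TransitionEstimates"))
  p <- c(p2 = estimates@p2, p3 = estimates@p3, p4 = estimates@p4,
         p5 = estimates@p5, p6 = estimates@p6)
  if (!is.null(digits)) p <- roundHalfUp(p, digits)
  p
}

#' Build the empirically parametrized memory chain
#'
#' Assembles the four-state chain from estimated transition probabilities
#' via [buildRawChain()], ready for the downstream absorption and spectral
#' analyses.
#'
#' @param estimates a [TransitionEstimates-class].
#' @return a [MemoryChain-class].
#' @export
#' @examples
#' buildEmpiricalChain(estimateTransitions(intrusionDiaryMeans()))
buildEmpiricalChain <- function(estimates) {
  stopifnot(is(estimates, "TransitionEstimates"))
  validObject(estimates)
  buildRawChain(p2 = estimates@p2, p3 = estimates@p3, p4 = estimates@p4,
                p5 = estimates@p5, p6 = estimates@p6)
}
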