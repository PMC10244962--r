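#' Generate synthetic intrusion diaries
#'
#' Simulates per-participant intrusion-count diaries with the structure of
#' the four-arm reminder-cue/task experiment: every participant has a
#' pre-intervention 24 h count drawn with the common `preMean` (the arms
#' are exchangeable before treatment) and a one-week count drawn with
#' their arm's mean. Counts are Poisson by default; setting `dispersion`
#' switches the week counts to negative binomial with that size parameter
#' (variance `mu + mu^2/size`) for robustness studies.
#'
#' @param preMean pre-intervention 24 h mean count (all arms).
#' @param groupMeans named numeric of week means per arm (the four arms of
#'   [memoryStates()]'s experiment: `no_task_control`, `cue_plus_task`,
#'   `task_only`, `cue_only`).
#' @param nPerGroup participants per arm (default 18, the order of
#'   magnitude implied by the published standard errors).
#' @param seed integer seed.
#' @param dispersion optional negative-binomial size; `NULL` keeps Poisson.
#' @return a [DiaryDataset-class].
#' @export
#' @examples
#' d <- generateDiaries(seed = 1)
#' head(diaryRecords(d))
generateDiaries <- function(preMean = 3.334,
                            groupMeans = c(no_task_control = 5.111,
                                           cue_plus_task = 1.889,
                                           task_only = 3.83,
                                           cue_only = 4.889),
                            nPerGroup = 18L, seed = 1L,
                            dispersion = NULL) {
  if (!is.numeric(preMean) || preMean < 0) .stopf("preMean must be >= 0")
  groupMeans <- unlist(groupMeans)
  if (!all(.DIARY_GROUPS %in% names(groupMeans)) || any(groupMeans < 0))
    .stopf("groupMeans must be non-negative and cover the four arms")
  if (!is.numeric(nPerGroup) || nPerGroup < 1)
    .stopf("nPerGroup must be >= 1")
  nPerGroup <- as.integer(nPerGroup)
  set.seed(as.integer(seed))
  recs <- lapply(.DIARY_GROUPS, function(g) {
    ids <- sprintf("%s_%03d", g, seq_len(nPerGroup))
    pre <- stats::rpois(nPerGroup, preMean)
    wk <- if (is.null(dispersion)) stats::rpois(nPerGroup, groupMeans[[g]])
          else stats::rnbinom(nPerGroup, size = dispersion,
                              mu = groupMeans[[g]])
    data.frame(participant_id = rep(ids, 2L),
               group = g,
               period = rep(c("pre24h", "week"), each = nPerGroup),
               count = c(pre, wk),
               stringsAsFactors = FALSE)
  })
  new("DiaryDataset", records = do.call(rbind, recs),
      generatingMeans = list(preMean = preMean,
                             groupMeans = groupMeans[.DIARY_GROUPS]),
      seed = as.integer(seed))
}

#' Summarize intrusion diaries into group means
#'
#' Computes the pooled pre-intervention mean (across all arms) and the
#' per-arm one-week means with standard errors (sample SD / sqrt(n); NA
#' for single-participant groups), producing the [DiarySummary-class]
#' consumed by [estimateTransitions()].
#'
#' @param dataset a [DiaryDataset-class] or a data.frame with columns
#'   `participant_id`, `group`, `period`, `count`.
#' @return a [DiarySummary-class].
#' @export
#' @examples
#' summarizeDiaries(generateDiaries(nPerGroup = 100, seed = 1))
summarizeDiaries <- function(dataset) {
  rec <- if (is(dataset, "DiaryDataset")) diaryRecords(dataset) else dataset
  if (!is.data.frame(rec) || !nrow(rec))
    .stopf("cannot summarize an empty diary dataset")
  need <- c("group", "period", "count")
  if (!all(need %in% names(rec)))
    .stopf("diary records need columns %s", paste(need, collapse = ", "))
  for (g in .DIARY_GROUPS)
    if (!any(rec$group == g & rec$period == "week"))
      .stopf("no week records for group '%s'", g)
  pre <- rec$count[rec$period == "pre24h"]
  if (!length(pre)) .stopf("no pre24h records in the dataset")
  seOf <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  means <- ses <- ns <- stats::setNames(numeric(length(.DIARY_GROUPS)), .DIARY_GROUPS)
  for (g in .DIARY_GROUPS) {
    x <- rec$count[rec$group == g & rec$period == "week"]
    means[g] <- mean(x); ses[g] <- seOf(x); ns[g] <- length(x)
  }
  diarySummary(preMean = mean(pre), preSE = seOf(pre),
               groupMeans = means, groupSE = ses, groupN = ns)
}

#' Estimator recovery experiment on synthetic diaries
#'
#' Repeats generate -> summarize -> estimate over `nReps` replicates and
#' reports, for each transition probability, the bias and root-mean-square
#' error of the estimates against the infinite-sample values implied by
#' the generating means. Demonstrates consistency of the Poisson
#' parametrization.
#'
#' @inheritParams generateDiaries
#' @param nReps number of replicates (>= 1).
#' @return list with `truth` (named vector), `bias`, `rmse`, `estimates`
#'   (nReps x 5 matrix), `nPerGroup`, `nReps`.
#' @export
#' @examples
#' recoveryExperiment(nPerGroup = 200, nReps = 10, seed = 1)$bias
recoveryExperiment <- function(preMean = 3.334,
                               groupMeans = c(no_task_control = 5.111,
                                              cue_plus_task = 1.889,
                                              task_only = 3.83,
                                              cue_only = 4.889),
                               nPerGroup = 1000L, nReps = 200L, seed = 1L) {
  if (!is.numeric(nReps) || nReps < 1) .stopf("nReps must be >= 1")
  nReps <- as.integer(nReps)
  truth <- transitionProbs(estimateTransitions(
    diarySummary(preMean, groupMeans)))
  est <- matrix(NA_real_, nReps, 5L,
                dimnames = list(NULL, names(truth)))
  for (r in seq_len(nReps)) {
    d <- generateDiaries(preMean, groupMeans, nPerGroup,
                         seed = as.integer(seed) + r - 1L)
    est[r, ] <- transitionProbs(estimateTransitions(summarizeDiaries(d)))
  }
  list(truth = truth,
       bias = colMeans(est) - truth,
       rmse = sqrt(colMeans(sweep(est, 2L, truth)^2)),
       estimates = est,
       nPerGroup = as.integer(nPerGroup), nReps = nReps)
}
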