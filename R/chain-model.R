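#' Reconsolidation probability under one or more task interventions
#'
#' Probability that a reactivated intrusive memory reconsolidates back into
#' the intrusive state under task interventions of strengths `T_i` acting
#' multiplicatively: `1 / prod(1 + T_i)`. With no effective task (all
#' strengths zero) reconsolidation is certain; the probability is
#' non-increasing in every strength.
#'
#' @param taskStrengths numeric vector of non-negative task strengths.
#' @return a probability in (0, 1].
#' @export
#' @examples
#' taskReconsolidationProb(0)        # 1: no task
#' taskReconsolidationProb(1)        # 0.5
#' taskReconsolidationProb(c(1, 1))  # 0.25: two tasks multiplicatively
taskReconsolidationProb <- function(taskStrengths) {
  if (!is.numeric(taskStrengths) || !length(taskStrengths) ||
      anyNA(taskStrengths) || any(taskStrengths < 0))
    .stopf("task strengths must be non-negative numbers")
  1 / prod(1 + taskStrengths)
}

#' Reactivation probability of a reminder cue
#'
#' Logistic probability that a single reminder cue of strength `alpha`
#' reactivates a consolidated intrusive memory: `1 / (1 + exp(-alpha))`.
#' Strictly increasing in `alpha`, with value 1/2 at zero strength.
#'
#' @param cueStrength finite cue strength (any real).
#' @return a probability in (0, 1).
#' @export
#' @examples
#' cueReactivationProb(0)    # 0.5
#' cueReactivationProb(0.5)  # ~0.6225
cueReactivationProb <- function(cueStrength) {
  if (!is.numeric(cueStrength) || length(cueStrength) != 1L ||
      !is.finite(cueStrength))
    .stopf("cue strength must be a single finite number")
  stats::plogis(cueStrength)
}

#' Reactivation probability under multiple reminder cues
#'
#' Extends [cueReactivationProb()] to several cues. Under the
#' `independent` model all `n` cues must fire, giving
#' `plogis(alpha)^n` (strictly decreasing in `n`). Under the `nested`
#' model cues taper conditionally: the logistic is self-composed `n` times
#' starting from `alpha`, converging monotonically to the logistic fixed
#' point (~0.659046). `single` ignores `n` and returns the one-cue value.
#'
#' @param cueStrength finite cue strength.
#' @param model `"single"`, `"independent"` or `"nested"`.
#' @param n integer >= 1; number of cues or nesting depth.
#' @return a probability.
#' @export
#' @examples
#' multiCueProb(0.5, "independent", 5)  # ~0.0934
#' multiCueProb(0.5, "nested", 3)       # ~0.6572
multiCueProb <- function(cueStrength,
                         model = c("single", "independent", "nested"),
                         n = 1L) {
  if (length(model) != 1L || !model %in% c("single", "independent", "nested"))
    .stopf("unknown cue model '%s': use 'single', 'independent' or 'nested'",
           paste(model, collapse = ","))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    .stopf("cue count/depth n must be a single integer >= 1")
  p <- cueReactivationProb(cueStrength)
  switch(model,
    single = p,
    independent = p^n,
    nested = {
      x <- cueStrength
      for (i in seq_len(n)) x <- stats::plogis(x)
      x
    })
}

# reactivated-state row under the normalized task+cue construction:
# reconsolidation weight r = 1/prod(1+T_i) competes with the unit mass split
# p4 : (1-p4); dividing by s = 1 + r always yields a valid distribution
.reactivatedRow <- function(taskStrengths, labilityProb) {
  r <- taskReconsolidationProb(taskStrengths)
  s <- 1 + r
  c(0, r / s, labilityProb / s, (1 - labilityProb) / s)
}

#' Build the task-plus-cue memory chain
#'
#' Constructs the canonical four-state chain from intervention parameters.
#' The iM row is `(0, 1 - p3, p3, 0)` with the reactivation probability
#' `p3` given by the configured cue model; the reactivated row is
#' `(0, r/s, p4/s, (1 - p4)/s)` with \eqn{r = 1/\prod_i(1 + T_i)} and
#' \eqn{s = 1 + r},
#' so that the task competes with lability and the row is always a valid
#' distribution. `pre_trauma` consolidates with probability 1 and `niM` is
#' absorbing.
#'
#' @param params an [InterventionParams-class], or `NULL` to build one from
#'   the remaining arguments.
#' @inheritParams interventionParams
#' @return a [MemoryChain-class].
#' @export
#' @examples
#' buildTaskCueChain(taskStrengths = 1, cueStrength = 0.5, labilityProb = 0.5)
buildTaskCueChain <- function(params = NULL, taskStrengths = 0,
                              cueStrength = 0.5, labilityProb = 0.5,
                              cueModel = c("single", "independent", "nested"),
                              cueCount = 1L) {
  if (is.null(params))
    params <- interventionParams(taskStrengths, cueStrength, labilityProb,
                                 match.arg(cueModel), cueCount)
  stopifnot(is(params, "InterventionParams"))
  validObject(params)
  p3 <- multiCueProb(params@cueStrength, params@cueModel, params@cueCount)
  M <- rbind(c(0, 1, 0, 0),
             c(0, 1 - p3, p3, 0),
             .reactivatedRow(params@taskStrengths, params@labilityProb),
             c(0, 0, 0, 1))
  memoryChain(M, params = list(taskStrengths = params@taskStrengths,
                               cueStrength = params@cueStrength,
                               labilityProb = params@labilityProb,
                               cueModel = params@cueModel,
                               cueCount = params@cueCount),
              tol = 1e-12)
}

#' Build the fixed no-cue/no-task baseline chain
#'
#' The comparator chain used without the reminder cue and the task
#' intervention: iM row `(0, 0.5, 0.5, 0)` and reactivated row
#' `(0, 0.33, 0.34, 0.33)`.
#'
#' @return a [MemoryChain-class].
#' @export
#' @examples
#' buildBaselineChain()
buildBaselineChain <- function() {
  M <- rbind(c(0, 1, 0, 0),
             c(0, 0.5, 0.5, 0),
             c(0, 0.33, 0.34, 0.33),
             c(0, 0, 0, 1))
  memoryChain(M, params = list(kind = "baseline"), tol = 1e-12)
}

#' Build a chain from directly supplied transition probabilities
#'
#' Assembles the four-state chain from the five free probabilities: the iM
#' row `(0, p2, p3, 0)` and the reactivated row `(0, p5, p4, p6)`. Used by
#' the empirical parametrization path. Rows must sum to 1 within 1e-9.
#'
#' @param p2 probability an intrusive memory reconsolidates unaltered.
#' @param p3 probability an intrusive memory is reactivated.
#' @param p4 probability a reactivated memory stays reactivated.
#' @param p5 probability a reactivated memory reconsolidates as intrusive.
#' @param p6 probability a reactivated memory reconsolidates non-intrusive.
#' @return a [MemoryChain-class].
#' @export
#' @examples
#' buildRawChain(0.5, 0.5, 0.34, 0.33, 0.33)
buildRawChain <- function(p2, p3, p4, p5, p6) {
  p2 <- unname(p2); p3 <- unname(p3); p4 <- unname(p4)
  p5 <- unname(p5); p6 <- unname(p6)
  for (nm in c("p2", "p3", "p4", "p5", "p6"))
    .assertProb(get(nm), nm)
  if (abs(p2 + p3 - 1) > 1e-9)
    .stopf("row iM invalid: p2 + p3 = %.12g, must equal 1", p2 + p3)
  if (abs(p4 + p5 + p6 - 1) > 1e-9)
    .stopf("row reactivated invalid: p4 + p5 + p6 = %.12g, must equal 1",
           p4 + p5 + p6)
  M <- rbind(c(0, 1, 0, 0),
             c(0, p2, p3, 0),
             c(0, p5, p4, p6),
             c(0, 0, 0, 1))
  memoryChain(M, params = list(p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6),
              tol = 1e-9)
}
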