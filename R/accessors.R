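#' @describeIn MemoryChain-class constructor from a 4x4 matrix. Dimnames are
#'   attached (and checked when already present); `tol` is the
#'   row-stochasticity tolerance — internal constructors use 1e-12, matrices
#'   arriving from files are accepted at 1e-9 and re-normalized exactly.
#' @param matrix 4x4 numeric matrix of transition probabilities.
#' @param params optional list of construction provenance.
#' @param tol row-sum tolerance for the supplied matrix.
#' @export
memoryChain <- function(matrix, params = list(), tol = 1e-9) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(4L, 4L)))
    .stopf("a MemoryChain needs a 4x4 matrix, got %s",
           paste(dim(matrix), collapse = "x"))
  if (!is.null(dimnames(matrix)) &&
      (!identical(rownames(matrix), .STATES) ||
       !identical(colnames(matrix), .STATES)))
    .stopf("matrix dimnames must be (%s) in order", paste(.STATES, collapse = ", "))
  dimnames(matrix) <- list(.STATES, .STATES)
  rs <- rowSums(matrix)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    .stopf("row '%s' sums to %.12g, not 1 (tolerance %g)",
           .STATES[bad[1]], rs[bad[1]], tol)
  if (anyNA(matrix) || any(matrix < -tol) || any(matrix > 1 + tol))
    .stopf("transition probabilities must lie in [0, 1]")
  matrix <- pmin(pmax(matrix, 0), 1)
  matrix <- matrix / rowSums(matrix)  # exact row-stochasticity
  new("MemoryChain", transitionMatrix = matrix, params = params)
}

#' Accessors for MemoryChain objects
#'
#' `transitionMatrix()` returns the 4x4 row-stochastic matrix,
#' `chainStates()` the ordered state labels, `chainParams()` the
#' construction provenance, and `transitionProb()` a single labelled entry.
#'
#' @param object a [MemoryChain-class].
#' @return see individual descriptions.
#' @name chain-accessors
#' @aliases transitionMatrix chainStates chainParams transitionProb
#' @examples
#' ch <- buildBaselineChain()
#' transitionMatrix(ch)
#' transitionProb(ch, "reactivated", "niM")
NULL

#' @rdname chain-accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname chain-accessors
#' @export
setMethod("transitionMatrix", "MemoryChain", function(object) object@transitionMatrix)

#' @rdname chain-accessors
#' @export
setGeneric("chainStates", function(object) standardGeneric("chainStates"))

#' @rdname chain-accessors
#' @export
setMethod("chainStates", "MemoryChain", function(object) rownames(object@transitionMatrix))

#' @rdname chain-accessors
#' @export
setGeneric("chainParams", function(object) standardGeneric("chainParams"))

#' @rdname chain-accessors
#' @export
setMethod("chainParams", "MemoryChain", function(object) object@params)

#' @rdname chain-accessors
#' @param from,to state labels.
#' @export
transitionProb <- function(object, from, to) {
  stopifnot(is(object, "MemoryChain"))
  from <- match.arg(from, .STATES)
  to <- match.arg(to, .STATES)
  object@transitionMatrix[from, to]
}

setMethod("show", "MemoryChain", function(object) {
  cat("MemoryChain (4-state absorbing intrusive-memory chain)\n")
  print(round(object@transitionMatrix, 6))
  p <- object@params
  if (length(p)) {
    cat("constructed from:",
        paste(names(p), vapply(p, function(x) paste(format(x), collapse = ","),
                               character(1)), sep = "=", collapse = "; "),
        "\n")
  }
  invisible(object)
})

#' @describeIn InterventionParams-class constructor with domain checks.
#' @param taskStrengths numeric vector of task strengths, all >= 0.
#' @param cueStrength reminder-cue strength (finite real).
#' @param labilityProb probability a reactivated memory stays reactivated.
#' @param cueModel `"single"`, `"independent"` or `"nested"`.
#' @param cueCount number of cues (independent) or nesting depth (nested).
#' @export
interventionParams <- function(taskStrengths = 0, cueStrength = 0.5,
                               labilityProb = 0.5,
                               cueModel = c("single", "independent", "nested"),
                               cueCount = 1L) {
  cueModel <- match.arg(cueModel)
  new("InterventionParams", taskStrengths = as.numeric(taskStrengths),
      cueStrength = as.numeric(cueStrength),
      labilityProb = as.numeric(labilityProb),
      cueModel = cueModel, cueCount = as.integer(cueCount))
}

setMethod("show", "InterventionParams", function(object) {
  cat(sprintf(
    "InterventionParams: T=(%s), alpha=%g, p4=%g, cue model=%s (n=%d)\n",
    paste(format(object@taskStrengths), collapse = ", "),
    object@cueStrength, object@labilityProb, object@cueModel,
    object@cueCount))
  invisible(object)
})

#' @describeIn StateDistribution-class constructor; `probs` may be unnamed
#'   (state order is assumed) or named by state.
#' @param probs numeric vector of 4 probabilities summing to 1.
#' @param step time step the distribution refers to.
#' @export
stateDistribution <- function(probs, step = 0L) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L)
    .stopf("a StateDistribution needs 4 probabilities, got %d", length(probs))
  names(probs) <- .STATES
  new("StateDistribution", probs = probs, step = as.integer(step))
}

#' @rdname StateDistribution-class
#' @param object a `StateDistribution`.
#' @export
setGeneric("stateProbs", function(object) standardGeneric("stateProbs"))

#' @rdname StateDistribution-class
#' @export
setMethod("stateProbs", "StateDistribution", function(object) object@probs)

setMethod("show", "StateDistribution", function(object) {
  cat(sprintf("StateDistribution at step %d\n", object@step))
  print(round(object@probs, 6))
  invisible(object)
})

setMethod("show", "SpectralSummary", function(object) {
  cat("SpectralSummary\n")
  cat("  eigenvalue moduli:", paste(format(Mod(object@eigenvalues), digits = 6),
                                    collapse = ", "), "\n")
  cat(sprintf("  |lambda2| = %.6f, relaxation time = %.4f steps\n",
              object@secondModulus, object@relaxationTime))
  if (!object@diagonalizable)
    cat("  note: eigenbasis ill-conditioned; powers use direct multiplication\n")
  invisible(object)
})

setMethod("show", "AbsorptionSummary", function(object) {
  cat("AbsorptionSummary (expected visits before absorption into niM)\n")
  print(round(object@fundamental, 4))
  cat("expected steps to absorption:\n")
  print(round(object@timeToAbsorption, 4))
  invisible(object)
})

#' Accessors for AbsorptionSummary objects
#'
#' @param object an [AbsorptionSummary-class].
#' @name absorption-accessors
NULL

#' @rdname absorption-accessors
#' @export
setGeneric("fundamental", function(object) standardGeneric("fundamental"))

#' @rdname absorption-accessors
#' @export
setMethod("fundamental", "AbsorptionSummary", function(object) object@fundamental)

#' @rdname absorption-accessors
#' @export
setGeneric("timeToAbsorption", function(object) standardGeneric("timeToAbsorption"))

#' @rdname absorption-accessors
#' @export
setMethod("timeToAbsorption", "AbsorptionSummary", function(object) object@timeToAbsorption)

#' Accessors for SpectralSummary objects
#'
#' @param object a [SpectralSummary-class].
#' @name spectral-accessors
NULL

#' @rdname spectral-accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname spectral-accessors
#' @export
setMethod("eigenvalues", "SpectralSummary", function(object) object@eigenvalues)

#' @rdname spectral-accessors
#' @export
setGeneric("relaxationTime", function(object) standardGeneric("relaxationTime"))

#' @rdname spectral-accessors
#' @export
setMethod("relaxationTime", "SpectralSummary", function(object) object@relaxationTime)

setMethod("show", "TransitionEstimates", function(object) {
  cat("TransitionEstimates (Poisson parametrization of the memory chain)\n")
  p <- c(p2 = object@p2, p3 = object@p3, p4 = object@p4,
         p5 = object@p5, p6 = object@p6)
  print(roundHalfUp(p, 3))
  cat("(values rounded half-up to 3 d.p.; slots keep full precision)\n")
  cat("note: the estimator assumes exchangeable pre-intervention baselines",
      "across arms;\ncheck baseline comparability externally before use.\n")
  invisible(object)
})

setMethod("show", "DiarySummary", function(object) {
  cat(sprintf("DiarySummary: pooled pre-intervention mean %.3f (SE %s)\n",
              object@preMean,
              ifelse(is.na(object@preSE), "NA", sprintf("%.3f", object@preSE))))
  df <- data.frame(group = names(object@groupMeans),
                   mean = as.numeric(object@groupMeans),
                   se = as.numeric(object@groupSE[names(object@groupMeans)]),
                   n = as.numeric(object@groupN[names(object@groupMeans)]))
  print(df, row.names = FALSE)
  invisible(object)
})

setMethod("show", "DiaryDataset", function(object) {
  rec <- object@records
  cat(sprintf("DiaryDataset: %d records, %d participants\n",
              nrow(rec), length(unique(rec$participant_id))))
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
  invisible(object)
})

#' @rdname DiaryDataset-class
#' @param object a `DiaryDataset`.
#' @export
setGeneric("diaryRecords", function(object) standardGeneric("diaryRecords"))

#' @rdname DiaryDataset-class
#' @export
setMethod("diaryRecords", "DiaryDataset", function(object) object@records)

setMethod("show", "DoseSchedule", function(object) {
  cat(sprintf("DoseSchedule over %d steps, %d segment(s)\n",
              object@horizon, length(object@segments)))
  for (s in object@segments)
    cat(sprintf("  steps %d..%d\n", s$from, s$to))
  invisible(object)
})

setMethod("show", "LHSDesign", function(object) {
  cat(sprintf("LHSDesign: %d samples x %d parameters (seed %d)\n",
              nrow(object@samples), ncol(object@samples), object@seed))
  for (j in names(object@ranges))
    cat(sprintf("  %s in [%g, %g]\n", j, object@ranges[[j]][1],
                object@ranges[[j]][2]))
  invisible(object)
})

#' @rdname LHSDesign-class
#' @param object an `LHSDesign`.
#' @export
setGeneric("designSamples", function(object) standardGeneric("designSamples"))

#' @rdname LHSDesign-class
#' @export
setMethod("designSamples", "LHSDesign", function(object) object@samples)
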