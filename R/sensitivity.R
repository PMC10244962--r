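#' Default sensitivity-analysis parameter ranges
#'
#' The ranges swept in the mixing-time sensitivity analysis: lability
#' probability `p4` in \[0, 1\], task strength `T` in \[0, 20\] and
#' reminder-cue strength `alpha` in \[0, 1\].
#'
#' @return named list of c(low, high) ranges.
#' @export
#' @examples
#' defaultSensitivityRanges()
defaultSensitivityRanges <- function() {
  list(p4 = c(0, 1), T = c(0, 20), alpha = c(0, 1))
}

#' Latin hypercube sample over parameter ranges
#'
#' Draws a stratified design: for each parameter, exactly one sample falls
#' in each of `n` equal-width strata of its range. Uses [lhs::randomLHS()]
#' under the given seed, then scales the unit hypercube to the ranges.
#'
#' @param n number of samples (>= 2).
#' @param ranges named list of c(low, high) per parameter; defaults to
#'   [defaultSensitivityRanges()].
#' @param seed integer seed.
#' @return an [LHSDesign-class].
#' @export
#' @examples
#' lhsSample(10, seed = 1)
lhsSample <- function(n, ranges = defaultSensitivityRanges(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    .stopf("n must be a single integer >= 2")
  if (!is.list(ranges) || is.null(names(ranges)) || !length(ranges))
    .stopf("ranges must be a named list of c(low, high)")
  for (j in names(ranges)) {
    r <- ranges[[j]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      .stopf("invalid range for '%s': need finite low < high", j)
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n, length(ranges))
  X <- vapply(seq_along(ranges), function(j) {
    r <- ranges[[j]]
    r[1] + U[, j] * (r[2] - r[1])
  }, numeric(n))
  colnames(X) <- names(ranges)
  new("LHSDesign", samples = X, ranges = ranges, seed = as.integer(seed))
}

#' Cue-strength to reactivation coupling for sensitivity sweeps
#'
#' Scales the logistic reactivation function so that zero cue strength
#' reproduces a chosen baseline reactivation rate exactly:
#' `p3 = min(1, p3Base * plogis(alpha) / plogis(0))`. With
#' `p3Base = 0.5` this is the plain logistic; other baselines scale it
#' proportionally, allowing sweeps at low background reactivation rates
#' (e.g. 0.05) that the logistic alone cannot reach.
#'
#' @param alpha cue strength (vectorized).
#' @param p3Base baseline reactivation probability at `alpha = 0`.
#' @return reactivation probability (clipped at 1).
#' @export
#' @examples
#' cueCoupledReactivation(0, 0.5)    # 0.5
#' cueCoupledReactivation(1, 0.05)   # ~0.0731
cueCoupledReactivation <- function(alpha, p3Base) {
  pmin(1, p3Base * stats::plogis(alpha) / 0.5)
}

.coupledP3 <- cueCoupledReactivation

#' Mixing-time response over an LHS design
#'
#' For each sampled parameter set (p4, T, alpha), builds the task-plus-cue
#' chain — reactivated row from the normalized task construction, and
#' iM-to-reactivated probability `p3 = min(1, p3Base * plogis(alpha)/0.5)`,
#' which reduces to the plain logistic when `p3Base = 0.5` and scales the
#' baseline reactivation rate proportionally otherwise — and computes its
#' mixing time. Rows whose chain has no finite mixing time are recorded as
#' missing with the error message.
#'
#' @param design an [LHSDesign-class] with columns `p4`, `T`, `alpha`.
#' @param p3Base baseline reactivation probability in (0, 1).
#' @return data.frame with columns `p4`, `T`, `alpha`, `tau`, `note`.
#' @export
#' @examples
#' mixingResponse(lhsSample(20, seed = 1), p3Base = 0.5)
mixingResponse <- function(design, p3Base = 0.5) {
  stopifnot(is(design, "LHSDesign"))
  if (!is.numeric(p3Base) || length(p3Base) != 1L || p3Base <= 0 ||
      p3Base >= 1)
    .stopf("p3Base must be a single probability strictly inside (0, 1)")
  X <- designSamples(design)
  need <- c("p4", "T", "alpha")
  if (!all(need %in% colnames(X)))
    .stopf("design must have columns %s", paste(need, collapse = ", "))
  n <- nrow(X)
  tau <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p3 <- unname(.coupledP3(X[i, "alpha"], p3Base))
    r <- taskReconsolidationProb(unname(X[i, "T"]))
    s <- 1 + r
    res <- tryCatch({
      ch <- buildRawChain(p2 = 1 - p3, p3 = p3,
                          p4 = X[i, "p4"] / s, p5 = r / s,
                          p6 = (1 - X[i, "p4"]) / s)
      mixingTime(ch)
    }, error = function(e) e)
    if (inherits(res, "error")) note[i] <- conditionMessage(res)
    else tau[i] <- res
  }
  data.frame(p4 = X[, "p4"], T = X[, "T"], alpha = X[, "alpha"],
             tau = tau, note = note, stringsAsFactors = FALSE)
}

#' Correlation summary of a sensitivity table
#'
#' Pearson (product-moment) correlation of each parameter column with the
#' mixing-time response, with missing rows excluded pairwise. Correlations
#' with |rho| below `weakThreshold` are classified `weak`, the others
#' `positive` or `negative` by sign.
#'
#' @param table data.frame as returned by [mixingResponse()].
#' @param response name of the response column (default `"tau"`).
#' @param weakThreshold |rho| below which a correlation is called weak.
#' @return data.frame with columns `parameter`, `rho`, `n`,
#'   `classification`.
#' @export
#' @examples
#' correlationSummary(mixingResponse(lhsSample(100, seed = 1), 0.5))
correlationSummary <- function(table, response = "tau", weakThreshold = 0.1) {
  params <- setdiff(names(table), c(response, "note"))
  y <- table[[response]]
  ok <- is.finite(y)
  if (sum(ok) < 3L)
    .stopf("need at least 3 complete rows to correlate, have %d", sum(ok))
  if (stats::sd(y[ok]) == 0)
    .stopf("undefined correlation: the response is constant")
  out <- lapply(params, function(j) {
    x <- table[[j]]
    use <- ok & is.finite(x)
    rho <- stats::cor(x[use], y[use])
    data.frame(parameter = j, rho = rho, n = sum(use),
               classification = if (abs(rho) < weakThreshold) "weak"
                                else if (rho > 0) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
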