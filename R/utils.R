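#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.0005 -> 0.001), as used when
#' presenting estimated transition probabilities. Base [round()] rounds
#' half to even, which is not the convention used for the printed estimates.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(0.0355, 3)
#' roundHalfUp(c(0.9643, 0.00539), 3)
roundHalfUp <- function(x, digits = 3) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  # nudge by one ulp so that values stored just under an exact .5 tie
  # (decimal literals are not exact binary) still round up
  sign(x) * floor(abs(x) * p + 0.5 + .Machine$double.eps * abs(x) * p) / p
}

# full-precision numeric formatting for text serialization; %.17g
# round-trips IEEE doubles exactly
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertProb <- function(x, name, tol = 1e-9) {
  if (!is.numeric(x) || anyNA(x) || any(x < -tol) || any(x > 1 + tol))
    .stopf("'%s' must be a probability in [0, 1], got %s", name,
           paste(format(x), collapse = ", "))
  pmin(pmax(x, 0), 1)
}
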