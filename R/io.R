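#' Read and write memory chains, trajectories and estimates
#'
#' Chains serialize to JSON as `{states: [...], matrix: [[...]]}` (full
#' IEEE precision, bit-exact round trip) and to labelled CSV (17
#' significant digits, value-exact round trip). Trajectories and
#' sensitivity sweeps use tidy CSV; transition estimates use JSON.
#'
#' @param chain a [MemoryChain-class].
#' @param path file path.
#' @return the written path (write functions, invisibly) or the restored
#'   object (read functions).
#' @name chain-io
#' @examples
#' p <- tempfile(fileext = ".json")
#' writeChainJSON(buildBaselineChain(), p)
#' readChainJSON(p)
NULL

#' @rdname chain-io
#' @export
writeChainJSON <- function(chain, path) {
  stopifnot(is(chain, "MemoryChain"))
  M <- transitionMatrix(chain)
  obj <- list(states = rownames(M),
              matrix = unname(apply(M, 1, as.numeric, simplify = FALSE)),
              params = chainParams(chain))
  # I(17) = 17 significant digits, enough to round-trip doubles bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname chain-io
#' @export
readChainJSON <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    .stopf("malformed chain JSON '%s': %s", path,
                           conditionMessage(e)))
  if (!all(c("states", "matrix") %in% names(obj)))
    .stopf("chain JSON '%s' must contain 'states' and 'matrix'", path)
  M <- obj$matrix
  if (is.list(M)) M <- do.call(rbind, M)
  M <- matrix(as.numeric(M), 4, 4, dimnames = list(obj$states, obj$states))
  memoryChain(M, params = if (is.null(obj$params)) list() else obj$params)
}

#' @rdname chain-io
#' @export
writeChainCSV <- function(chain, path) {
  stopifnot(is(chain, "MemoryChain"))
  M <- transitionMatrix(chain)
  df <- data.frame(state = rownames(M))
  for (j in colnames(M)) df[[j]] <- fmtNum(M[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname chain-io
#' @export
readChainCSV <- function(path) {
  df <- .readCsvStrict(path, c("state", .STATES))
  M <- as.matrix(df[, .STATES])
  storage.mode(M) <- "double"
  rownames(M) <- df$state
  memoryChain(M[.STATES, , drop = FALSE])
}

# read.csv with column and cell validation; names the offending row
.readCsvStrict <- function(path, requiredCols, numericCols = setdiff(requiredCols, c("state", "group", "period", "participant_id", "parameter", "classification", "note"))) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   .stopf("malformed CSV '%s': %s", path, conditionMessage(e)))
  miss <- setdiff(requiredCols, names(df))
  if (length(miss))
    .stopf("CSV '%s' is missing column(s): %s", path,
           paste(miss, collapse = ", "))
  for (j in intersect(numericCols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(df[[j]] %in% c("NA", "")) )
    if (length(bad))
      .stopf("CSV '%s': non-numeric value '%s' in column '%s' at data row %d",
             path, df[[j]][bad[1]], j, bad[1])
    df[[j]] <- v
  }
  df
}

#' Trajectory CSV round trip
#'
#' Trajectories are written tidy: one row per (step, state) with the
#' occupation probability at 17 significant digits.
#'
#' @param trajectory matrix from [evolve()].
#' @param path file path.
#' @name trajectory-io
NULL

#' @rdname trajectory-io
#' @export
writeTrajectoryCSV <- function(trajectory, path) {
  if (!is.matrix(trajectory) || !all(.STATES %in% colnames(trajectory)))
    .stopf("trajectory must be a matrix with the four state columns")
  steps <- as.integer(rownames(trajectory))
  df <- data.frame(step = rep(steps, times = 4L),
                   state = rep(.STATES, each = length(steps)),
                   probability = fmtNum(as.numeric(trajectory[, .STATES])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trajectory-io
#' @export
readTrajectoryCSV <- function(path) {
  df <- .readCsvStrict(path, c("step", "state", "probability"))
  steps <- sort(unique(df$step))
  out <- matrix(NA_real_, length(steps), 4L,
                dimnames = list(steps, .STATES))
  out[cbind(match(df$step, steps), match(df$state, .STATES))] <- df$probability
  if (anyNA(out))
    .stopf("trajectory CSV '%s' is incomplete: missing (step, state) cells", path)
  out
}

#' Sweep-table CSV round trip
#'
#' Writes any numeric data.frame (e.g. a [mixingResponse()] table) with
#' full-precision floats; reads it back value-exact.
#'
#' @param table data.frame.
#' @param path file path.
#' @param requiredCols columns that must be present when reading.
#' @name sweep-io
NULL

#' @rdname sweep-io
#' @export
writeSweepCSV <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in names(out)) if (is.numeric(out[[j]])) out[[j]] <- fmtNum(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sweep-io
#' @export
readSweepCSV <- function(path, requiredCols = c("p4", "T", "alpha", "tau")) {
  .readCsvStrict(path, requiredCols)
}

#' Diary CSV round trip
#'
#' Per-participant diary records: columns `participant_id`, `group`,
#' `period` (`pre24h` or `week`) and `count`.
#'
#' @param dataset a [DiaryDataset-class] or its records data.frame.
#' @param path file path.
#' @name diary-io
NULL

#' @rdname diary-io
#' @export
writeDiaryCSV <- function(dataset, path) {
  rec <- if (is(dataset, "DiaryDataset")) diaryRecords(dataset) else dataset
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname diary-io
#' @export
readDiaryCSV <- function(path) {
  df <- .readCsvStrict(path, c("participant_id", "group", "period", "count"),
                       numericCols = "count")
  if (all(df$count == floor(df$count))) df$count <- as.integer(df$count)
  new("DiaryDataset", records = df, generatingMeans = list(),
      seed = NA_integer_)
}

#' Transition-estimates JSON round trip
#'
#' @param estimates a [TransitionEstimates-class].
#' @param path file path.
#' @name estimates-io
NULL

#' @rdname estimates-io
#' @export
writeEstimatesJSON <- function(estimates, path) {
  stopifnot(is(estimates, "TransitionEstimates"))
  obj <- list(probabilities = as.list(transitionProbs(estimates)),
              rounded_3dp = as.list(transitionProbs(estimates, digits = 3)),
              intermediates = estimates@intermediates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname estimates-io
#' @export
readEstimatesJSON <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    .stopf("malformed estimates JSON '%s': %s", path,
                           conditionMessage(e)))
  p <- obj$probabilities
  new("TransitionEstimates", p2 = p$p2, p3 = p$p3, p4 = p$p4, p5 = p$p5,
      p6 = p$p6,
      intermediates = if (is.null(obj$intermediates)) list()
                      else as.list(obj$intermediates))
}
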