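# File formats: expression CSV/TSV (header row of gene names, one row per
# time point), dataset JSON sidecar, result/metrics JSON.

.delimFor <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an expression time series
#'
#' Expects a delimited text file with one header row of gene names and one
#' numeric row per time point; the delimiter is inferred from the extension
#' (comma for `.csv`, tab for `.tsv`/`.txt`).
#'
#' @param path file path.
#' @return K x n numeric matrix with gene names as column names.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = .delimFor(path),
                      check.names = FALSE, colClasses = "character"),
    error = function(e)
      stop(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) < 2L)
    stop(sprintf("format error in %s: at least 2 time points required (found %d)",
                 path, nrow(df)))
  Y <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("format error in %s: non-numeric cell at row %d, column '%s'",
                   path, bad, colnames(df)[j]))
    }
    Y[, j] <- v
  }
  message(sprintf("read %d time points x %d genes from %s",
                  nrow(Y), ncol(Y), path))
  Y
}

#' Write an expression time series
#'
#' Inverse of [readExpression()]: header row of gene names, one row per time
#' point, delimiter by extension.
#'
#' @param Y K x n matrix (column names used as gene labels, g1..gn when
#'   absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(Y, path) {
  Y <- as.matrix(Y)
  genes <- colnames(Y)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(Y)))
  colnames(Y) <- genes
  utils::write.table(Y, path, sep = .delimFor(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression CSV plus a JSON sidecar (`<prefix>.json`) holding
#' the ground-truth coefficient matrix, noise covariances, seed and initial
#' state, making the run reproducible from its artifacts.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] from
#'   [simulateGRN()].
#' @param prefix output path prefix (writes `<prefix>.csv`,
#'   `<prefix>.json`).
#' @return character vector of the written paths, invisibly.
#' @export
writeDataset <- function(se, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  writeExpression(expressionMatrix(se), csv)
  md <- S4Vectors::metadata(se)
  jsonlite::write_json(
    list(A_true = md$A_true, U = md$U, R = md$R, seed = md$seed, x0 = md$x0),
    js, digits = NA, matrix = "rowmajor")
  invisible(c(csv, js))
}

#' Write a fit result to disk
#'
#' Emits `<prefix>.json` (theta, coefficient matrix, history and the
#' resolved configuration including the seed), `<prefix>_adjacency.csv` and
#' `<prefix>_edges.tsv`.
#'
#' @param fit a [GRNFit-class].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
writeFit <- function(fit, prefix) {
  js <- paste0(prefix, ".json")
  adj <- paste0(prefix, "_adjacency.csv")
  edges <- paste0(prefix, "_edges.tsv")
  jsonlite::write_json(
    list(mode = fit@mode, theta = fit@theta, A = fit@A,
         converged = fit@converged, iterations = fit@iterations,
         history = fit@history, config = .jsonSafe(fit@config)),
    js, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  writeAdjacency(fit@A, adj)
  writeEdgeList(fit@A, edges)
  invisible(c(js, adj, edges))
}

# drop non-serializable config entries (functions etc.)
.jsonSafe <- function(x) {
  x[vapply(x, function(v) is.numeric(v) || is.character(v) || is.logical(v) ||
             is.matrix(v), logical(1))]
}
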