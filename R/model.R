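#' Build a state-space model
#'
#' Thin constructor for the [StateSpaceModel-class] contract
#' \eqn{x_k = f(x_{k-1},\theta) + u_k}, \eqn{y_k = h(x_k,\theta) + v_k}.
#'
#' @param transition function(x, theta) -> next-state mean vector.
#' @param measurement function(x, theta) -> observation mean vector.
#' @param stateDim,obsDim,thetaDim integer dimensions.
#' @param regressor optional function(x) -> \eqn{\phi(x)}; supply when the
#'   transition is linear in theta, \eqn{f(x,\theta) = A(\theta)\phi(x)},
#'   to enable the exact quadratic E/M path.
#' @param thetaInMeasurement does h depend on theta? When FALSE the
#'   measurement term of the EM objective is dropped.
#'
#' @return A [StateSpaceModel-class].
#' @export
stateSpaceModel <- function(transition, measurement, stateDim, obsDim,
                            thetaDim, regressor = NULL,
                            thetaInMeasurement = FALSE) {
  new("StateSpaceModel", transition = transition, measurement = measurement,
      regressor = regressor, stateDim = as.integer(stateDim),
      obsDim = as.integer(obsDim), thetaDim = as.integer(thetaDim),
      thetaInMeasurement = thetaInMeasurement)
}

#' Element-wise sigmoid link
#'
#' The regulation function \eqn{g(x) = 1/(1+e^{-x})}, applied element-wise.
#' Overflow-safe: large negative inputs are handled through the
#' \eqn{e^{x}/(1+e^{x})} branch so values up to |x| = 1e3 are exact 0/1
#' limits rather than NaN.
#'
#' @param x numeric vector or matrix.
#' @return values in (0, 1) with the shape of `x`.
#' @examples
#' sigmoidLink(0)        # 0.5
#' sigmoidLink(c(-1e3, 1e3))
#' @export
sigmoidLink <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' GRN transition map
#'
#' One step of the sigmoidal gene-regulation dynamics: \eqn{A\,g(x)} where
#' `A[i, j]` is the regulation coefficient from gene j to gene i (positive =
#' activation, negative = repression) and g is [sigmoidLink()].
#'
#' @param x state vector (expression levels).
#' @param A n x n regulatory coefficient matrix.
#' @return next-state mean vector of length n.
#' @export
grnTransition <- function(x, A) {
  if (length(x) != ncol(A))
    stop(sprintf("state length (%d) must match ncol(A) (%d)",
                 length(x), ncol(A)))
  drop(A %*% sigmoidLink(x))
}

#' GRN measurement map
#'
#' The identity observation model \eqn{y_k = x_k} (noise is added by the
#' simulator, not here).
#'
#' @param x state vector.
#' @return `x` unchanged.
#' @export
grnMeasurement <- function(x) x

#' Pack a coefficient matrix into a parameter vector (and back)
#'
#' The packing is row-major: the edge from gene j to gene i (entry
#' `A[i, j]`) maps to theta index `(i - 1) * n + j`. Every module uses this
#' one convention.
#'
#' @param A n x n coefficient matrix.
#' @return `packTheta`: numeric vector of length n^2.
#' @examples
#' packTheta(diag(2))          # 1 0 0 1
#' unpackTheta(c(1, 0, 0, 1), 2)
#' @export
packTheta <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  as.vector(t(A))
}

#' @rdname packTheta
#' @param theta packed parameter vector of length n^2.
#' @param n matrix dimension; defaults to `sqrt(length(theta))`.
#' @return `unpackTheta`: the n x n matrix.
#' @export
unpackTheta <- function(theta, n = NULL) {
  if (is.null(n)) {
    n <- sqrt(length(theta))
    if (n != floor(n))
      stop(sprintf("theta length (%d) is not a perfect square", length(theta)))
    n <- as.integer(n)
  }
  if (length(theta) != n * n)
    stop(sprintf("theta length (%d) does not equal n^2 (%d)",
                 length(theta), n * n))
  matrix(theta, nrow = n, ncol = n, byrow = TRUE)
}

#' Construct the sigmoidal GRN state-space model
#'
#' Transition \eqn{f(x, \theta) = A(\theta)\, g(x)} with the sigmoid link and
#' identity measurement. The model is linear in theta (regressor
#' [sigmoidLink()]), so the EM Q-function reduces to an exact quadratic, and
#' theta does not enter the measurement.
#'
#' @param n number of genes.
#' @return A [StateSpaceModel-class] with `thetaDim = n^2`.
#' @export
grnModel <- function(n) {
  n <- as.integer(n)
  stateSpaceModel(
    transition = function(x, theta) grnTransition(x, unpackTheta(theta, n)),
    measurement = function(x, theta) grnMeasurement(x),
    stateDim = n, obsDim = n, thetaDim = n * n,
    regressor = sigmoidLink,
    thetaInMeasurement = FALSE)
}

#' Read and write adjacency matrices and edge lists
#'
#' Adjacency matrices are stored as headered CSV with genes as both row and
#' column labels; edge lists as TSV with columns source, target, weight
#' (nonzero coefficients only, `A[target, source]`).
#'
#' @param A coefficient matrix (rownames/colnames used as gene labels; g1..gn
#'   supplied when absent).
#' @param path file path.
#' @return `readAdjacency` returns the labelled matrix; the writers return
#'   `path` invisibly.
#' @export
writeAdjacency <- function(A, path) {
  A <- as.matrix(A)
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(A)))
  dimnames(A) <- list(genes, genes)
  df <- data.frame(gene = genes, A, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAdjacency
#' @export
readAdjacency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  genes <- as.character(df[[1]])
  A <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(A)) stop("adjacency body must be numeric")
  dimnames(A) <- list(genes, colnames(A))
  A
}

#' @rdname writeAdjacency
#' @export
writeEdgeList <- function(A, path) {
  A <- as.matrix(A)
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(A)))
  idx <- which(A != 0, arr.ind = TRUE)
  df <- data.frame(source = genes[idx[, "col"]],
                   target = genes[idx[, "row"]],
                   weight = A[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
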