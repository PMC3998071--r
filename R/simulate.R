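# Synthetic GRN trajectory generation and the benchmark coefficient
# matrices.

.FIXTURES <- list(
  four_gene = matrix(c(
     3.0,  0.0, 0.0, -4.5,
    -2.9,  0.0, 5.0,  0.0,
    -6.0,  4.0, 0.0,  0.0,
     0.0, -5.0, 2.0,  0.0), nrow = 4, byrow = TRUE),
  four_gene_dense = matrix(c(
     3.0, -1.0, 0.0, -4.5,
    -2.9,  0.0, 5.0,  1.0,
    -6.0,  4.0, 0.0, -1.0,
     1.0, -5.0, 2.0,  0.0), nrow = 4, byrow = TRUE),
  eight_gene = matrix(c(
     0.0,  0.0,  0.0,  0.0,  0.0,  0.0,  2.4,  3.2,
     0.0,  0.0,  0.0,  4.1,  0.0, -2.4,  0.0,  4.1,
    -5.0,  2.1, -1.5,  0.0,  4.5,  0.0,  2.1,  0.0,
     0.0,  1.3,  2.5, -3.7,  1.8,  0.0,  0.0, -3.1,
     0.0,  0.0,  0.0, -2.6, -3.2,  0.0, -1.0,  4.0,
    -1.5, -1.8,  0.0,  3.4,  1.4,  1.1,  0.0,  1.7,
    -1.8,  0.0,  0.0, -3.0,  1.1,  2.4,  0.0,  0.0,
    -1.3,  0.0, -1.0,  0.0,  2.1,  0.0,  0.0,  2.2), nrow = 8, byrow = TRUE))

#' Benchmark regulatory coefficient matrices
#'
#' The fixed ground-truth networks used by the package's simulation
#' experiments: `four_gene` (4 x 4, 8 nonzero entries), `four_gene_dense`
#' (a denser 4 x 4 variant with 12 nonzeros) and `eight_gene` (8 x 8).
#'
#' @param name one of `"four_gene"`, `"four_gene_dense"`, `"eight_gene"`.
#' @return the n x n coefficient matrix with gene labels g1..gn.
#' @examples
#' fixtureA("four_gene")
#' @export
fixtureA <- function(name) {
  if (!name %in% names(.FIXTURES))
    stop(sprintf("unknown fixture '%s'; valid names: %s", name,
                 paste(names(.FIXTURES), collapse = ", ")))
  A <- .FIXTURES[[name]]
  genes <- paste0("g", seq_len(nrow(A)))
  dimnames(A) <- list(genes, genes)
  A
}

#' Simulate a GRN expression time series
#'
#' Generates \eqn{x_1 = x_0}; \eqn{x_k = A g(x_{k-1}) + u_k} for k >= 2;
#' \eqn{y_k = x_k + v_k} for all k, with u and v independent zero-mean
#' Gaussians. The default initial state is drawn once from N(0, I) under the
#' seed.
#'
#' @param A n x n regulatory coefficient matrix.
#' @param K number of time points (>= 2).
#' @param U,R noise covariances; scalar or matrix.
#' @param x0 initial state (default: standard-normal draw).
#' @param seed integer seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   `expression` (observed, genes x time) and `states` (noise-free of
#'   measurement noise, genes x time), and metadata `A_true`, `U`, `R`,
#'   `seed`, `x0`.
#' @examples
#' se <- simulateGRN(fixtureA("four_gene"), K = 10, seed = 1)
#' dim(expressionMatrix(se))   # 10 x 4
#' @export
simulateGRN <- function(A, K, U = 0.01, R = 0.01, x0 = NULL, seed = 1L) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (K < 2L) stop("K must be at least 2")
  Um <- .expandCov(U, n, "U")
  Rm <- .expandCov(R, n, "R")
  if (min(eigen(Um, symmetric = TRUE, only.values = TRUE)$values) < -1e-10 ||
      min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("noise covariances must be positive semidefinite")
  Su <- matrixSqrt(Um)
  Sr <- matrixSqrt(Rm)
  set.seed(seed)
  if (is.null(x0)) x0 <- stats::rnorm(n)
  X <- matrix(0, K, n)
  X[1L, ] <- x0
  for (k in 2:K)
    X[k, ] <- grnTransition(X[k - 1L, ], A) + drop(Su %*% stats::rnorm(n))
  V <- t(Sr %*% matrix(stats::rnorm(n * K), n, K))
  Y <- X + V
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = t(Y), states = t(X)),
    rowData = S4Vectors::DataFrame(gene = genes, row.names = genes),
    colData = S4Vectors::DataFrame(time = seq_len(K),
                                   row.names = paste0("t", seq_len(K))))
  S4Vectors::metadata(se) <- list(A_true = A, U = Um, R = Rm,
                                  seed = as.integer(seed), x0 = x0)
  se
}

#' Extract matrices from a simulated dataset
#'
#' `expressionMatrix` returns the observations as a K x n matrix (rows =
#' time points) as consumed by [runEM()]; `trueStates` the noise-free-of-
#' measurement states in the same layout; `trueCoefficients` the generating
#' matrix (NULL for loaded data without ground truth).
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment].
#' @return a matrix (or NULL).
#' @export
expressionMatrix <- function(se) {
  t(SummarizedExperiment::assay(se, "expression"))
}

#' @rdname expressionMatrix
#' @export
trueStates <- function(se) {
  if (!"states" %in% SummarizedExperiment::assayNames(se)) return(NULL)
  t(SummarizedExperiment::assay(se, "states"))
}

#' @rdname expressionMatrix
#' @export
trueCoefficients <- function(se) S4Vectors::metadata(se)$A_true

.PRESETS <- list(
  four_gene_lownoise = list(fixture = "four_gene", K = 20L, U = 0.01,
                            R = 0.01, initSd = sqrt(2)),
  four_gene_highnoise = list(fixture = "four_gene", K = 20L, U = 0.1,
                             R = 0.1, initSd = sqrt(2)),
  four_gene_K10 = list(fixture = "four_gene", K = 10L, U = 0.01, R = 0.01,
                       initSd = sqrt(2)),
  four_gene_K20 = list(fixture = "four_gene", K = 20L, U = 0.01, R = 0.01,
                       initSd = sqrt(2)),
  eight_gene_K40 = list(fixture = "eight_gene", K = 40L, U = 0.01, R = 0.01,
                        initSd = 1))

#' Preset experimental conditions
#'
#' Bundles of (ground-truth network, horizon, noise level, parameter
#' initialization SD) matching the package's benchmark settings: the 4-gene
#' network at low (0.01 I) and high (0.1 I) noise, horizons 10 and 20, and
#' the 8-gene network with 40 time points at noise 0.01 I.
#'
#' @param name preset identifier.
#' @return list with elements `A`, `K`, `U`, `R`, `initSd`, `name`.
#' @export
experimentPreset <- function(name) {
  if (!name %in% names(.PRESETS))
    stop(sprintf("unknown preset '%s'; valid names: %s", name,
                 paste(names(.PRESETS), collapse = ", ")))
  p <- .PRESETS[[name]]
  list(name = name, A = fixtureA(p$fixture), K = p$K, U = p$U, R = p$R,
       initSd = p$initSd)
}
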