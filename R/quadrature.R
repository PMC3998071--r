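#' Construct the unscented-transform quadrature rule
#'
#' Builds the 2n+1 sigma points for a standard n-dimensional Gaussian: the
#' origin with weight \eqn{\kappa/(n+\kappa)} and \eqn{\pm\sqrt{n+\kappa}\,e_i}
#' each with weight \eqn{1/(2(n+\kappa))}. The rule integrates polynomials of
#' total degree up to three exactly. With the default \eqn{\kappa = 0} the
#' origin carries weight zero (the point is still generated so the point-set
#' shape does not depend on \eqn{\kappa}); this coincides with the
#' spherical-radial cubature rule.
#'
#' @param n state dimension (positive integer).
#' @param kappa spread parameter; must satisfy `n + kappa > 0`. Negative
#'   values (e.g. -1 or -3 with large n) give a negative origin weight.
#'
#' @return A [QuadratureRule-class] object.
#' @examples
#' r <- utRule(2)
#' sum(quadWeights(r))  # 1
#' @export
utRule <- function(n, kappa = 0) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n must be a single positive integer")
  if (n + kappa <= 0)
    stop(sprintf("invalid rule: n + kappa must be positive (n = %d, kappa = %g)",
                 n, kappa))
  s <- sqrt(n + kappa)
  pts <- cbind(matrix(0, n, 1), s * diag(n), -s * diag(n))
  w <- c(kappa / (n + kappa), rep(1 / (2 * (n + kappa)), 2L * n))
  new("QuadratureRule", points = pts, weights = w,
      kappa = as.numeric(kappa), dim = n)
}

#' Factor a covariance matrix as P = S S'
#'
#' Cholesky factorization is attempted first; if it fails (numerically
#' singular P) a diagonal jitter of `1e-10 * trace(P)/n` is added and the
#' Cholesky retried; the symmetric-eigendecomposition factor
#' \eqn{U\sqrt{\Lambda}} is the deterministic last resort. Matrices with an
#' eigenvalue below \eqn{-10^{-8}\|P\|} are rejected as not positive
#' semidefinite.
#'
#' @param P symmetric positive-semidefinite matrix.
#' @return A matrix S (lower triangular when Cholesky succeeds) with
#'   `S %*% t(S)` equal to P up to floating-point error.
#' @examples
#' S <- matrixSqrt(diag(c(4, 9)))
#' S %*% t(S)
#' @export
matrixSqrt <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square")
  scl <- max(abs(P), 1)
  if (max(abs(P - t(P))) > 1e-8 * scl)
    stop("P must be symmetric (within tolerance)")
  Ps <- (P + t(P)) / 2
  n <- nrow(Ps)
  ev <- eigen(Ps, symmetric = TRUE, only.values = TRUE)$values
  nrm <- max(abs(ev))
  if (min(ev) < -1e-8 * max(nrm, 1))
    stop(sprintf("P is not positive semidefinite (min eigenvalue %g)", min(ev)))
  S <- tryCatch(t(chol(Ps)), error = function(e) NULL)
  jit <- 1e-10 * sum(diag(Ps)) / n
  if (is.null(S) && jit > 0)
    S <- tryCatch(t(chol(Ps + jit * diag(n))), error = function(e) NULL)
  if (is.null(S)) {
    ed <- eigen(Ps, symmetric = TRUE)
    S <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), n)
  }
  S
}

#' Approximate a Gaussian expectation with a quadrature rule
#'
#' Computes \eqn{E_{N(\hat x, P)}[g(x)] \approx \sum_i w_i g(S\gamma_i + \hat
#' x)} where \eqn{P = SS^T}. `g` may return a scalar, vector, or matrix; the
#' result has the same shape.
#'
#' @param g function of one state vector.
#' @param belief a [GaussianBelief-class] (or anything with `beliefMean`/
#'   `beliefCov` methods).
#' @param rule a [QuadratureRule-class] whose dimension matches the belief.
#'
#' @return the weighted sum of g over the transformed points.
#' @examples
#' b <- new("GaussianBelief", mean = 0, cov = matrix(1))
#' gaussianExpectation(function(x) x^2, b, utRule(1))  # second moment = 1
#' @export
gaussianExpectation <- function(g, belief, rule) {
  m <- beliefMean(belief)
  P <- beliefCov(belief)
  if (rule@dim != length(m))
    stop(sprintf("rule dimension (%d) must match belief dimension (%d)",
                 rule@dim, length(m)))
  S <- matrixSqrt(P)
  X <- S %*% rule@points + m
  w <- rule@weights
  acc <- NULL
  for (i in seq_along(w)) {
    gi <- g(X[, i])
    if (!all(is.finite(gi)))
      stop(sprintf("g returned a non-finite value at quadrature point %d", i))
    acc <- if (is.null(acc)) w[i] * gi else acc + w[i] * gi
  }
  acc
}

# Internal: evaluate a columnwise-vectorized map over the sigma points of a
# belief.  fmat takes an n x N matrix of points and returns a d x N matrix.
# Returns list(X = points, FX = values, w = weights, mean = belief mean).
.sigmaEval <- function(fmat, m, P, rule) {
  S <- matrixSqrt(P)
  X <- S %*% rule@points + m
  FX <- fmat(X)
  if (!all(is.finite(FX)))
    stop("non-finite value among sigma-point evaluations")
  list(X = X, FX = FX, w = rule@weights, mean = m)
}

# Internal: weighted mean of columns and weighted centered outer products.
.wmean <- function(M, w) drop(M %*% w)

.wcross <- function(A, a, B, b, w) {
  # sum_i w_i (A_i - a)(B_i - b)^T with columns as samples
  Ac <- A - a
  Bc <- B - b
  (Ac * rep(w, each = nrow(Ac))) %*% t(Bc)
}

.symmetrize <- function(P) (P + t(P)) / 2
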