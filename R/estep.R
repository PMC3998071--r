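# E-step: the (negated, to-be-minimized) Q-function.
#
# For transition models linear in theta, f(x, theta) = A phi(x), the
# transition part of the Q-function,
#   Qt(A) = sum_{k=2}^K E[ (x_k - A phi(x_{k-1}))' U^{-1} (x_k - A phi(x_{k-1})) ],
# is an exact quadratic in A determined by three moment matrices accumulated
# over the pairwise smoothed joints.  Expectations use the 2n-dimensional
# sigma-point rule on each joint; for the sigmoid regressor this inherits the
# degree-3 accuracy of the rule.

#' Accumulate Q-function sufficient statistics from a smoothed trace
#'
#' Requires a model with a declared regressor (transition linear in theta).
#' For each k = 1..K-1 the pairwise joint of \eqn{(x_k, x_{k+1})} is
#' integrated with a 2n-dimensional sigma-point rule to accumulate
#' \eqn{E[x_{k+1} x_{k+1}^T]}, \eqn{E[x_{k+1}\phi(x_k)^T]} and
#' \eqn{E[\phi(x_k)\phi(x_k)^T]}.
#'
#' @param trace a [SmoothTrace-class].
#' @param model a [StateSpaceModel-class] with non-NULL regressor.
#' @param U process-noise covariance (treated as known).
#' @param rule a [QuadratureRule-class] of dimension 2n.
#' @return a [QStatistics-class].
#' @export
qStatistics <- function(trace, model, U, rule) {
  if (is.null(model@regressor))
    stop("qStatistics requires a model with transition linear in theta (regressor set)")
  n <- trace@stateDim
  if (rule@dim != 2L * n)
    stop(sprintf("rule dimension must be 2n = %d (got %d)", 2L * n, rule@dim))
  K <- trace@nTime
  phi <- model@regressor
  Sxx <- matrix(0, n, n)
  Sxg <- matrix(0, n, n)
  Sgg <- matrix(0, n, n)
  for (k in seq_len(K - 1L)) {
    joint <- pairwiseJoint(trace, k)
    S <- matrixSqrt(beliefCov(joint))
    Z <- S %*% rule@points + beliefMean(joint)
    xk <- Z[seq_len(n), , drop = FALSE]
    xk1 <- Z[n + seq_len(n), , drop = FALSE]
    G <- phi(xk)
    w <- rule@weights
    xk1w <- xk1 * rep(w, each = n)
    Gw <- G * rep(w, each = n)
    Sxx <- Sxx + xk1w %*% t(xk1)
    Sxg <- Sxg + xk1w %*% t(G)
    Sgg <- Sgg + Gw %*% t(G)
  }
  Uinv <- solve(U)
  ck <- 0.5 * (determinant(U, logarithm = TRUE)$modulus[1] + n * log(2 * pi))
  new("QStatistics", Sxx = .symmetrize(Sxx), Sxg = Sxg,
      Sgg = .symmetrize(Sgg), Uinv = .symmetrize(Uinv),
      const = 2 * (K - 1) * ck, nTerms = as.integer(K - 1L))
}

#' Evaluate the quadratic Q-function
#'
#' \deqn{\tilde Q(\theta) = tr(U^{-1} S_{xx}) - 2\,tr(U^{-1} A S_{x\phi}^T)
#'   + tr(U^{-1} A S_{\phi\phi} A^T),}
#' with \eqn{A} unpacked from theta. This is the to-be-minimized transition
#' part of the EM objective; the measurement term is absent because the GRN
#' model declares theta out of the measurement.
#'
#' @param theta packed parameter vector.
#' @param stats a [QStatistics-class].
#' @return scalar value of the quadratic.
#' @export
qValue <- function(theta, stats) {
  n <- nrow(stats@Sxx)
  A <- unpackTheta(theta, n)
  UA <- stats@Uinv %*% A
  sum(stats@Uinv * stats@Sxx) - 2 * sum(UA * stats@Sxg) +
    sum((UA %*% stats@Sgg) * A)
}

#' Analytic gradient of the quadratic Q-function
#'
#' \eqn{\nabla_A \tilde Q = 2 U^{-1}(A S_{\phi\phi} - S_{x\phi})}, packed
#' row-major to match [packTheta()].
#'
#' @inheritParams qValue
#' @return gradient vector of length n^2.
#' @export
qGradient <- function(theta, stats) {
  n <- nrow(stats@Sxx)
  A <- unpackTheta(theta, n)
  packTheta(2 * stats@Uinv %*% (A %*% stats@Sgg - stats@Sxg))
}

#' Direct quadrature evaluation of the Q-function
#'
#' The generic path: integrates
#' \eqn{(x_{k+1} - f(x_k,\theta))^T U^{-1} (x_{k+1} - f(x_k,\theta))} over
#' each pairwise smoothed joint with the 2n-dimensional rule. Works for any
#' transition (no linear-in-theta requirement); for linear-in-theta models it
#' agrees with [qValue()] built from [qStatistics()] because both use the
#' same rule on the same joints.
#'
#' @inheritParams qStatistics
#' @param theta packed parameter vector at which to evaluate.
#' @return scalar value.
#' @export
qValueDirect <- function(theta, trace, model, U, rule) {
  n <- trace@stateDim
  if (rule@dim != 2L * n)
    stop(sprintf("rule dimension must be 2n = %d (got %d)", 2L * n, rule@dim))
  Uinv <- solve(U)
  total <- 0
  for (k in seq_len(trace@nTime - 1L)) {
    joint <- pairwiseJoint(trace, k)
    g <- function(z) {
      r <- z[n + seq_len(n)] - model@transition(z[seq_len(n)], theta)
      drop(crossprod(r, Uinv %*% r))
    }
    total <- total + gaussianExpectation(g, joint, rule)
  }
  total
}

#' Finite-difference gradient of the direct Q-function
#'
#' Central-difference fallback for models without an analytic quadratic
#' form.
#'
#' @inheritParams qValueDirect
#' @param h step size.
#' @return numeric gradient vector.
#' @export
qGradientNumeric <- function(theta, trace, model, U, rule, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (qValueDirect(tp, trace, model, U, rule) -
       qValueDirect(tm, trace, model, U, rule)) / (2 * h)
  }, numeric(1))
}
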