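# Backward Gaussian approximation smoother (RTS form).
#
# The pairwise joint of (x_k, x_{k+1}) given all data is Gaussian with cross
# block D_k P~_{k+1}, where D_k = C_k P_{k+1|k}^{-1} is the smoother gain and
# C_k the filtered-stage cross covariance.  The terminal condition copies the
# last filtered belief exactly.

#' Filtered-stage cross covariance
#'
#' \eqn{C_k = E[(x - \hat x_{k|k})(f(x) - \hat x_{k+1|k})^T]} under the
#' filtered belief at time k, approximated by sigma-point quadrature.
#'
#' @param filtered filtered [GaussianBelief-class] at time k.
#' @param predictedNext predicted [GaussianBelief-class] at time k+1.
#' @param model,theta,rule as in [predictBelief()].
#' @return the n x n cross-covariance matrix.
#' @export
crossCovariance <- function(filtered, predictedNext, model, theta, rule) {
  n <- model@stateDim
  m <- beliefMean(filtered)
  ev <- .sigmaEval(function(X) .colApply(model@transition, X, theta, n),
                   m, beliefCov(filtered), rule)
  .wcross(ev$X, m, ev$FX, beliefMean(predictedNext), ev$w)
}

#' One backward smoothing step
#'
#' Given the filtered belief at k, the predicted belief and smoothed belief
#' at k+1, and the cross covariance \eqn{C_k}, computes the smoother gain
#' \eqn{D_k = C_k P_{k+1|k}^{-1}} (by linear solve, not explicit inverse) and
#' the smoothed moments
#' \deqn{\tilde x_k = \hat x_{k|k} + D_k(\tilde x_{k+1} - \hat x_{k+1|k}),}
#' \deqn{\tilde P_k = P_{k|k} + D_k(\tilde P_{k+1} - P_{k+1|k})D_k^T.}
#'
#' @param filtered,predictedNext,smoothedNext [GaussianBelief-class] objects.
#' @param Ck cross covariance from [crossCovariance()].
#' @return list with `belief` (smoothed [GaussianBelief-class] at k) and
#'   `gain` (the matrix \eqn{D_k}).
#' @export
smoothStep <- function(filtered, predictedNext, smoothedNext, Ck) {
  Pp <- beliefCov(predictedNext)
  D <- tryCatch(t(solve(Pp, t(Ck))), error = function(e)
    stop(sprintf("predicted covariance is singular in the smoother: %s",
                 conditionMessage(e))))
  m <- beliefMean(filtered) +
    drop(D %*% (beliefMean(smoothedNext) - beliefMean(predictedNext)))
  P <- .symmetrize(beliefCov(filtered) +
                     D %*% (beliefCov(smoothedNext) - Pp) %*% t(D))
  list(belief = new("GaussianBelief", mean = m, cov = P), gain = D)
}

#' Backward smoothing pass
#'
#' Initializes at k = K with the filtered belief (terminal identity), then
#' recurses k = K-1..1, storing the smoother gains and cross covariances
#' needed to rebuild each pairwise joint.
#'
#' @param forward a [FilterTrace-class] from [forwardPass()].
#' @param model,theta,rule as in [predictBelief()].
#' @return a [SmoothTrace-class].
#' @export
backwardPass <- function(forward, model, theta, rule) {
  K <- forward@nTime
  n <- forward@stateDim
  means <- matrix(0, K, n)
  covs <- vector("list", K)
  gains <- vector("list", K - 1L)
  cross <- vector("list", K - 1L)
  sm <- filteredBelief(forward, K)
  means[K, ] <- beliefMean(sm)
  covs[[K]] <- beliefCov(sm)
  for (k in seq(K - 1L, 1L)) {
    fk <- filteredBelief(forward, k)
    pk1 <- predictedBelief(forward, k + 1L)
    Ck <- crossCovariance(fk, pk1, model, theta, rule)
    st <- smoothStep(fk, pk1, sm, Ck)
    sm <- st$belief
    means[k, ] <- beliefMean(sm)
    covs[[k]] <- beliefCov(sm)
    gains[[k]] <- st$gain
    cross[[k]] <- Ck
  }
  new("SmoothTrace", means = means, covs = covs, gains = gains,
      cross = cross, nTime = K, stateDim = n)
}

#' Pairwise smoothed joint of consecutive states
#'
#' Assembles the 2n-dimensional Gaussian of \eqn{(x_k, x_{k+1})} given all
#' observations: mean \eqn{(\tilde x_k, \tilde x_{k+1})}, diagonal blocks
#' \eqn{\tilde P_k}, \eqn{\tilde P_{k+1}}, upper-right cross block
#' \eqn{D_k \tilde P_{k+1}} (transposed lower-left). The result is
#' symmetrized and checked for indefiniteness.
#'
#' @param trace a [SmoothTrace-class].
#' @param k time index in 1..K-1.
#' @return a [GaussianBelief-class] of dimension 2n.
#' @export
pairwiseJoint <- function(trace, k) {
  K <- trace@nTime
  if (k < 1L || k > K - 1L)
    stop(sprintf("k must be in 1..%d", K - 1L))
  n <- trace@stateDim
  D <- trace@gains[[k]]
  Pk1 <- trace@covs[[k + 1L]]
  crossBlock <- D %*% Pk1
  J <- rbind(cbind(trace@covs[[k]], crossBlock),
             cbind(t(crossBlock), Pk1))
  J <- .symmetrize(J)
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    stop(sprintf("pairwise joint covariance at k = %d is indefinite (min eig %g)",
                 k, min(ev)))
  new("GaussianBelief",
      mean = c(trace@means[k, ], trace@means[k + 1L, ]), cov = J)
}
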