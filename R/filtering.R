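# Forward point-based Gaussian approximation filter.
#
# Prediction propagates the filtered belief through the transition by
# sigma-point quadrature; the update assimilates one observation through the
# quadrature-approximated joint of (x_k, y_k).  All covariances are
# symmetrized as (P + P')/2 after assembly.

# columnwise application of a model map over an n x N point matrix
.colApply <- function(fn, X, theta, d) {
  N <- ncol(X)
  out <- matrix(0, d, N)
  for (i in seq_len(N)) out[, i] <- fn(X[, i], theta)
  out
}

#' One-step prediction of a Gaussian belief
#'
#' Propagates the filtered belief at time k-1 to the predicted belief at
#' time k: mean \eqn{E[f(x)]} and covariance
#' \eqn{E[(f(x)-\bar f)(f(x)-\bar f)^T] + U}, both approximated with the
#' supplied sigma-point rule.
#'
#' @param belief filtered [GaussianBelief-class] at time k-1.
#' @param model a [StateSpaceModel-class].
#' @param theta packed parameter vector.
#' @param U process-noise covariance (symmetric PSD).
#' @param rule [QuadratureRule-class] of the state dimension.
#' @return the predicted [GaussianBelief-class].
#' @export
predictBelief <- function(belief, model, theta, U, rule) {
  n <- model@stateDim
  ev <- .sigmaEval(function(X) .colApply(model@transition, X, theta, n),
                   beliefMean(belief), beliefCov(belief), rule)
  m <- .wmean(ev$FX, ev$w)
  P <- .symmetrize(.wcross(ev$FX, m, ev$FX, m, ev$w) + U)
  new("GaussianBelief", mean = m, cov = P)
}

#' Measurement update of a predicted belief
#'
#' Computes the predicted observation \eqn{\hat y_{k|k-1}}, the cross and
#' innovation covariances \eqn{P^{xy}}, \eqn{P^{yy}} by quadrature, the gain
#' \eqn{L_k = P^{xy}(R + P^{yy})^{-1}}, and the filtered moments
#' \eqn{\hat x_{k|k} = \hat x_{k|k-1} + L_k(y_k - \hat y_{k|k-1})},
#' \eqn{P_{k|k} = P_{k|k-1} - L_k (P^{xy})^T}.
#'
#' @param predicted predicted [GaussianBelief-class] at time k.
#' @param y observation vector at time k.
#' @param model,theta,rule as in [predictBelief()].
#' @param R measurement-noise covariance.
#' @return a list with components `predicted`, `filtered` (beliefs),
#'   `predObs`, `gain`, `Pxy`, `Pyy`.
#' @export
updateBelief <- function(predicted, y, model, theta, R, rule) {
  d <- model@obsDim
  if (length(y) != d)
    stop(sprintf("observation length (%d) must equal obsDim (%d)", length(y), d))
  m <- beliefMean(predicted)
  ev <- .sigmaEval(function(X) .colApply(model@measurement, X, theta, d),
                   m, beliefCov(predicted), rule)
  yhat <- .wmean(ev$FX, ev$w)
  Pyy <- .symmetrize(.wcross(ev$FX, yhat, ev$FX, yhat, ev$w))
  Pxy <- .wcross(ev$X, m, ev$FX, yhat, ev$w)
  Sinn <- .symmetrize(R + Pyy)
  L <- tryCatch(t(solve(Sinn, t(Pxy))), error = function(e)
    stop(sprintf("innovation covariance R + Pyy is singular: %s",
                 conditionMessage(e))))
  mf <- m + drop(L %*% (y - yhat))
  Pf <- .symmetrize(beliefCov(predicted) - L %*% t(Pxy))
  list(predicted = predicted,
       filtered = new("GaussianBelief", mean = mf, cov = Pf),
       predObs = yhat, gain = L, Pxy = Pxy, Pyy = Pyy)
}

#' Forward filtering pass over an observation sequence
#'
#' Installs the initial belief as the filtered belief at k = 1 (the state is
#' initialized from the first measurement; no update is applied there), then
#' alternates prediction and measurement update for k = 2..K.
#'
#' @param Y K x obsDim observation matrix (rows = time points).
#' @param model a [StateSpaceModel-class].
#' @param theta packed parameter vector.
#' @param U,R process- and measurement-noise covariances.
#' @param init initial [GaussianBelief-class] at k = 1.
#' @param rule [QuadratureRule-class] of the state dimension.
#' @return a [FilterTrace-class].
#' @export
forwardPass <- function(Y, model, theta, U, R, init, rule) {
  Y <- as.matrix(Y)
  K <- nrow(Y)
  if (K < 2L) stop("at least K = 2 time points are required")
  if (!all(is.finite(Y))) {
    bad <- which(!apply(is.finite(Y), 1L, all))[1L]
    stop(sprintf("non-finite observation at time index %d", bad))
  }
  steps <- vector("list", K)
  steps[[1L]] <- list(predicted = init, filtered = init,
                      predObs = NULL, gain = NULL, Pxy = NULL, Pyy = NULL)
  for (k in 2:K) {
    pred <- predictBelief(steps[[k - 1L]]$filtered, model, theta, U, rule)
    steps[[k]] <- updateBelief(pred, Y[k, ], model, theta, R, rule)
  }
  new("FilterTrace", steps = steps, stateDim = model@stateDim,
      nTime = as.integer(K))
}
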