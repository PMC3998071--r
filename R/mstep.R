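# M-step: minimize value(theta) + 2 ||lam o theta||_1 by iterative soft
# thresholding with Barzilai-Borwein step sizes, optionally re-weighting the
# penalty between runs.

#' Soft thresholding (prox of the weighted L1 norm)
#'
#' `sign(u) * max(|u| - a, 0)` element-wise; exact zeros wherever
#' `|u| <= a`.
#'
#' @param u numeric vector.
#' @param a nonnegative threshold vector (recycled).
#' @return thresholded vector.
#' @examples
#' softThreshold(c(2, -3, 0.1), 1)   # 1 -2 0
#' @export
softThreshold <- function(u, a) {
  if (any(a < 0)) stop("thresholds must be nonnegative")
  sign(u) * pmax(abs(u) - a, 0)
}

#' Barzilai-Borwein step size
#'
#' \eqn{\alpha = s^T r / s^T s} from the parameter difference s and gradient
#' difference r; falls back to the safeguard value 1 when \eqn{s^T r \le 0}
#' or s = 0 (the least-squares fit of a scalar Hessian surrogate is then
#' meaningless).
#'
#' @param s parameter step \eqn{\theta^t - \theta^{t-1}}.
#' @param r gradient difference.
#' @return scalar step size.
#' @export
bbStep <- function(s, r) {
  if (length(s) != length(r)) stop("s and r must have the same length")
  ss <- sum(s * s)
  sr <- sum(s * r)
  if (ss == 0 || sr <= 0) return(1)
  sr / ss
}

#' Iterative soft thresholding with BB steps
#'
#' Minimizes \eqn{J(\theta) = value(\theta) + 2\|\lambda \circ \theta\|_1}
#' by the proximal iteration
#' \eqn{\theta^{t+1} = \eta_S(\theta^t - \nabla/\alpha_t,\; 2\lambda/\alpha_t)}.
#' The first step uses \eqn{\alpha_0 = 1}; later steps use [bbStep()]
#' clipped to \eqn{[10^{-8}, 10^{8}]}. Iteration stops when the relative
#' objective change falls below `tol` or at `maxIter`.
#'
#' @param valueFn function(theta) -> smooth objective value.
#' @param gradFn function(theta) -> its gradient.
#' @param lam nonnegative penalty rate vector (recycled to length(theta0)).
#' @param theta0 starting point.
#' @param tol relative objective-change tolerance.
#' @param maxIter iteration cap.
#' @return list with `theta`, `objective` (final J), `iterations`,
#'   `converged`.
#' @export
iterativeThresholding <- function(valueFn, gradFn, lam, theta0,
                                  tol = 1e-6, maxIter = 500L) {
  if (tol <= 0) stop("tol must be positive")
  m <- length(theta0)
  lam <- rep_len(lam, m)
  if (any(lam < 0)) stop("lambda rates must be nonnegative")
  pen <- function(th) 2 * sum(lam * abs(th))
  theta <- theta0
  grad <- gradFn(theta)
  J <- valueFn(theta) + pen(theta)
  if (!is.finite(J)) stop("objective is non-finite at the starting point")
  alpha <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    u <- theta - grad / alpha
    thetaNew <- softThreshold(u, 2 * lam / alpha)
    Jnew <- valueFn(thetaNew) + pen(thetaNew)
    if (!is.finite(Jnew))
      stop(sprintf("divergence: objective became non-finite at inner iteration %d (last finite J = %g)",
                   iter, J))
    gradNew <- gradFn(thetaNew)
    s <- thetaNew - theta
    r <- gradNew - grad
    rel <- abs(Jnew - J) / max(abs(J), .Machine$double.xmin)
    theta <- thetaNew
    grad <- gradNew
    J <- Jnew
    # the objective test only applies once a BB step exists: the fixed
    # alpha_0 = 1 first step can land on an equal-objective reflection of
    # the start without being anywhere near a minimizer
    if (iter >= 2L && rel <= tol) { converged <- TRUE; break }
    alpha <- min(max(bbStep(s, r), 1e-8), 1e8)
  }
  list(theta = theta, objective = J, iterations = iter, converged = converged)
}

#' Update the penalty rates from the current estimate
#'
#' The adaptive re-weighting rule \eqn{\lambda_i = 1/(|\theta_i| +
#' \epsilon)}: large coefficients get a small rate (little shrinkage bias),
#' small ones a large rate (pushed to exact zero).
#'
#' @param theta current parameter vector.
#' @param eps small positive constant preventing division by zero.
#' @return vector of rates.
#' @export
reweightLambda <- function(theta, eps = 0.01) {
  if (eps <= 0) stop("eps must be positive")
  1 / (abs(theta) + eps)
}

#' Construct a sparsity prior
#'
#' @param mode `"em"` (no penalty), `"rem"` (fixed rates), or `"rem_w"`
#'   (adaptive re-weighting).
#' @param lam scalar or vector of rates for mode `"rem"` (broadcast to all
#'   parameters); ignored in the other modes.
#' @param epsReweight the re-weighting epsilon.
#' @return a [SparsePrior-class].
#' @export
sparsePrior <- function(mode = c("rem_w", "rem", "em"), lam = 1,
                        epsReweight = 0.01) {
  mode <- match.arg(mode)
  new("SparsePrior", lam = as.numeric(lam), mode = mode,
      epsReweight = epsReweight)
}

#' M-step of the regularized EM
#'
#' Minimizes the quadratic Q-function plus the sparsity penalty.
#' Mode `"em"` solves the unpenalized normal equations
#' \eqn{A = S_{x\phi} S_{\phi\phi}^{-1}} in closed form. Mode `"rem"` runs
#' one [iterativeThresholding()] with the prior's fixed rates. Mode
#' `"rem_w"` starts from \eqn{\lambda_i = 1}, alternates thresholding runs
#' with [reweightLambda()], and stops when the sup-norm parameter change
#' between rounds drops below `rwTol` or after `rwMaxRounds` rounds.
#'
#' @param stats a [QStatistics-class] from [qStatistics()].
#' @param prior a [SparsePrior-class].
#' @param thetaPrime warm start (the current EM iterate).
#' @param innerTol,innerMaxIter tolerance and cap for each thresholding run.
#' @param rwTol,rwMaxRounds outer re-weighting controls.
#' @return list with `theta`, `objective` (penalized, at the final rates),
#'   `innerIterations` (total), `lam` (rates last used).
#' @export
mStep <- function(stats, prior, thetaPrime,
                  innerTol = 1e-6, innerMaxIter = 500L,
                  rwTol = 1e-6, rwMaxRounds = 10L) {
  m <- length(thetaPrime)
  valueFn <- function(th) qValue(th, stats)
  gradFn <- function(th) qGradient(th, stats)
  if (prior@mode == "em") {
    n <- nrow(stats@Sxx)
    A <- t(solve(stats@Sgg, t(stats@Sxg)))
    theta <- packTheta(A)
    return(list(theta = theta, objective = valueFn(theta),
                innerIterations = 0L, lam = rep(0, m)))
  }
  if (prior@mode == "rem") {
    lam <- rep_len(prior@lam, m)
    res <- iterativeThresholding(valueFn, gradFn, lam, thetaPrime,
                                 tol = innerTol, maxIter = innerMaxIter)
    return(list(theta = res$theta, objective = res$objective,
                innerIterations = res$iterations, lam = lam))
  }
  # rem_w: re-weighted rounds
  lam <- rep(1, m)
  theta <- thetaPrime
  totalInner <- 0L
  objective <- NA_real_
  for (round in seq_len(rwMaxRounds)) {
    res <- iterativeThresholding(valueFn, gradFn, lam, theta,
                                 tol = innerTol, maxIter = innerMaxIter)
    totalInner <- totalInner + res$iterations
    objective <- res$objective
    delta <- max(abs(res$theta - theta))
    theta <- res$theta
    if (round > 1L && delta < rwTol) break
    lam <- reweightLambda(theta, prior@epsReweight)
  }
  list(theta = theta, objective = objective,
       innerIterations = totalInner, lam = lam)
}
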