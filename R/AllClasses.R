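#' @import methods
NULL

setClassUnion("functionOrNULL", members = c("function", "NULL"))

#' Sigma-point quadrature rule for standard-Gaussian expectations
#'
#' A weighted point set \eqn{\{(\gamma_i, w_i)\}} approximating
#' \eqn{E_{N(0,I)}[g(x)] \approx \sum_i w_i g(\gamma_i)}. The unscented
#' construction uses \eqn{2n+1} points: the origin plus
#' \eqn{\pm\sqrt{n+\kappa}\,e_i} along each coordinate axis, and is exact for
#' polynomials of total degree up to three.
#'
#' @slot points n x N numeric matrix; column i is the point \eqn{\gamma_i}.
#' @slot weights length-N numeric vector summing to one (entries may be
#'   negative when \eqn{\kappa < 0}).
#' @slot kappa the spread parameter \eqn{\kappa}; must satisfy
#'   \eqn{n + \kappa > 0}.
#' @slot dim the state dimension n.
#'
#' @seealso [utRule()], [gaussianExpectation()]
#' @export
setClass("QuadratureRule",
  slots = c(points = "matrix", weights = "numeric",
            kappa = "numeric", dim = "integer"))

setValidity("QuadratureRule", function(object) {
  n <- object@dim
  msg <- character()
  if (length(n) != 1L || n < 1L)
    msg <- c(msg, "dim must be a single positive integer")
  if (n + object@kappa <= 0)
    msg <- c(msg, sprintf("n + kappa must be positive (got %g)", n + object@kappa))
  if (ncol(object@points) != 2L * n + 1L)
    msg <- c(msg, "point set must contain 2n+1 points")
  if (nrow(object@points) != n)
    msg <- c(msg, "points must have n rows")
  if (length(object@weights) != ncol(object@points))
    msg <- c(msg, "one weight per point required")
  if (!all(is.finite(object@points)) || !all(is.finite(object@weights)))
    msg <- c(msg, "points and weights must be finite")
  else if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Gaussian state belief
#'
#' Mean vector and covariance matrix of the state at one time index, under a
#' stated conditioning set (e.g. predicted \eqn{x_{k|k-1}} or filtered
#' \eqn{x_{k|k}}).
#'
#' @slot mean numeric mean vector.
#' @slot cov symmetric positive-semidefinite covariance matrix.
#'
#' @export
setClass("GaussianBelief", slots = c(mean = "numeric", cov = "matrix"))

setValidity("GaussianBelief", function(object) {
  n <- length(object@mean)
  P <- object@cov
  msg <- character()
  if (!all(dim(P) == c(n, n)))
    msg <- c(msg, "cov must be square and match the mean dimension")
  else {
    if (!all(is.finite(object@mean)) || !all(is.finite(P)))
      msg <- c(msg, "mean and cov must be finite")
    else {
      asym <- max(abs(P - t(P)))
      scl <- max(abs(P), 1)
      if (asym > 1e-8 * scl)
        msg <- c(msg, sprintf("cov is asymmetric (max |P - t(P)| = %g)", asym))
      else {
        ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8 * max(abs(ev), 1))
          msg <- c(msg, sprintf("cov has a negative eigenvalue (%g)", min(ev)))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Discrete-time nonlinear state-space model
#'
#' The model contract \eqn{x_k = f(x_{k-1}, \theta) + u_k},
#' \eqn{y_k = h(x_k, \theta) + v_k}. When `regressor` is non-NULL the
#' transition is declared linear in the packed parameter vector:
#' \eqn{f(x, \theta) = A(\theta)\,\phi(x)} with \eqn{\phi} the regressor,
#' which enables the closed-form sufficient-statistics E/M path.
#'
#' @slot transition function(x, theta) returning the next-state mean.
#' @slot measurement function(x, theta) returning the observation mean.
#' @slot regressor function(x) (or NULL) giving \eqn{\phi(x)} for models
#'   with \eqn{f(x,\theta) = A(\theta)\phi(x)}.
#' @slot stateDim,obsDim,thetaDim integer dimensions.
#' @slot thetaInMeasurement logical; FALSE when h does not depend on theta,
#'   in which case the measurement term drops from the EM objective.
#'
#' @seealso [grnModel()], [stateSpaceModel()]
#' @export
setClass("StateSpaceModel",
  slots = c(transition = "function", measurement = "function",
            regressor = "functionOrNULL",
            stateDim = "integer", obsDim = "integer", thetaDim = "integer",
            thetaInMeasurement = "logical"))

setValidity("StateSpaceModel", function(object) {
  msg <- character()
  if (object@stateDim < 1L) msg <- c(msg, "stateDim must be >= 1")
  if (object@obsDim < 1L) msg <- c(msg, "obsDim must be >= 1")
  if (object@thetaDim < 1L) msg <- c(msg, "thetaDim must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Forward filter trace
#'
#' Output of [forwardPass()]: one step per time index holding predicted and
#' filtered beliefs plus the update by-products (predicted observation, gain,
#' cross- and innovation covariances) needed by the smoother and the E-step.
#'
#' @slot steps list of length K; each element a list with components
#'   `predicted`, `filtered` (both [GaussianBelief-class]), `predObs`,
#'   `gain`, `Pxy`, `Pyy` (NULL at k = 1, where the initial belief is
#'   installed without a measurement update).
#' @slot stateDim,nTime integer dimensions.
#'
#' @export
setClass("FilterTrace",
  slots = c(steps = "list", stateDim = "integer", nTime = "integer"))

setValidity("FilterTrace", function(object) {
  if (length(object@steps) != object@nTime)
    return("steps length must equal nTime")
  if (object@nTime < 2L) return("a filter trace needs K >= 2 time points")
  TRUE
})

#' Smoothed state trace
#'
#' Output of [backwardPass()]: smoothed marginal means/covariances for
#' k = 1..K plus the smoother gains \eqn{D_k} and filtered-stage cross
#' covariances \eqn{C_k} (k = 1..K-1) from which the pairwise smoothed joint
#' of \eqn{(x_k, x_{k+1})} is assembled.
#'
#' @slot means K x n matrix of smoothed means (row k = \eqn{\tilde x_k}).
#' @slot covs list of K smoothed covariances \eqn{\tilde P_k}.
#' @slot gains list of K-1 smoother gain matrices \eqn{D_k}.
#' @slot cross list of K-1 cross-covariance matrices \eqn{C_k}.
#' @slot nTime,stateDim integer dimensions.
#'
#' @seealso [pairwiseJoint()]
#' @export
setClass("SmoothTrace",
  slots = c(means = "matrix", covs = "list", gains = "list", cross = "list",
            nTime = "integer", stateDim = "integer"))

setValidity("SmoothTrace", function(object) {
  K <- object@nTime
  msg <- character()
  if (nrow(object@means) != K) msg <- c(msg, "means must have K rows")
  if (length(object@covs) != K) msg <- c(msg, "covs must have K elements")
  if (length(object@gains) != K - 1L) msg <- c(msg, "gains must have K-1 elements")
  if (length(object@cross) != K - 1L) msg <- c(msg, "cross must have K-1 elements")
  if (length(msg)) msg else TRUE
})

#' Sufficient statistics of the EM Q-function
#'
#' For transition models linear in the packed parameters,
#' \eqn{f(x,\theta) = A\,\phi(x)}, the (negated, to-be-minimized) Q-function
#' is an exact quadratic in A determined by the smoothed-joint expectations
#' \deqn{S_{xx} = \sum_k E[x_k x_k^T], \quad
#'       S_{x\phi} = \sum_k E[x_k \phi(x_{k-1})^T], \quad
#'       S_{\phi\phi} = \sum_k E[\phi(x_{k-1}) \phi(x_{k-1})^T],}
#' with sums over k = 2..K and expectations under the pairwise smoothed
#' joints.
#'
#' @slot Sxx,Sxg,Sgg the accumulated moment matrices (Sxg = \eqn{S_{x\phi}},
#'   Sgg = \eqn{S_{\phi\phi}}).
#' @slot Uinv inverse process-noise covariance.
#' @slot const theta-independent constant (normalization terms), reported
#'   for diagnostics and excluded from optimization.
#' @slot nTerms number of transition terms summed (K - 1).
#'
#' @export
setClass("QStatistics",
  slots = c(Sxx = "matrix", Sxg = "matrix", Sgg = "matrix",
            Uinv = "matrix", const = "numeric", nTerms = "integer"))

setValidity("QStatistics", function(object) {
  msg <- character()
  sym <- function(M) max(abs(M - t(M))) <= 1e-8 * max(abs(M), 1)
  if (!sym(object@Sxx)) msg <- c(msg, "Sxx must be symmetric")
  if (!sym(object@Sgg)) msg <- c(msg, "Sgg must be symmetric")
  if (object@nTerms < 1L) msg <- c(msg, "nTerms must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Sparsity-inducing prior on the packed parameters
#'
#' Per-parameter Laplace rates \eqn{\lambda_i} and the re-weighting policy.
#' Mode `"em"` means no penalty (\eqn{\lambda \equiv 0}), `"rem"` a fixed
#' \eqn{\lambda}, and `"rem_w"` adaptive re-weighting
#' \eqn{\lambda_i = 1/(|\theta_i| + \epsilon)} between thresholding runs.
#'
#' @slot lam numeric vector of nonnegative rates (recycled to the parameter
#'   dimension where needed).
#' @slot mode one of `"em"`, `"rem"`, `"rem_w"`.
#' @slot epsReweight the small positive \eqn{\epsilon} in the re-weighting
#'   formula.
#'
#' @seealso [sparsePrior()], [mStep()]
#' @export
setClass("SparsePrior",
  slots = c(lam = "numeric", mode = "character", epsReweight = "numeric"))

setValidity("SparsePrior", function(object) {
  msg <- character()
  if (!object@mode %in% c("em", "rem", "rem_w"))
    msg <- c(msg, "mode must be one of 'em', 'rem', 'rem_w'")
  if (any(object@lam < 0)) msg <- c(msg, "lambda rates must be nonnegative")
  if (object@epsReweight <= 0) msg <- c(msg, "epsReweight must be positive")
  if (length(msg)) msg else TRUE
})

#' Fitted regularized-EM model
#'
#' Result of [runEM()] (or of the baseline fitters, which populate the same
#' container): the final packed parameter vector, its matrix form for GRN
#' models, the per-iteration history, and the resolved configuration.
#'
#' @slot theta final packed parameter estimate.
#' @slot A the estimate reshaped to the coefficient matrix (row i, column j =
#'   regulation of gene i by gene j) when the parameters pack a square
#'   matrix; otherwise a 0 x 0 matrix.
#' @slot mode estimation mode used (`"em"`, `"rem"`, `"rem_w"`, `"l1"`,
#'   `"bpdn_df"`).
#' @slot history data.frame with one row per EM iteration plus the
#'   initialization row: columns `iteration`, `objective` (penalized M-step
#'   objective), `change` (relative parameter change), `innerIterations`.
#' @slot converged logical convergence flag.
#' @slot iterations number of EM iterations performed.
#' @slot config resolved configuration list (includes the seed).
#'
#' @export
setClass("GRNFit",
  slots = c(theta = "numeric", A = "matrix", mode = "character",
            history = "data.frame", converged = "logical",
            iterations = "integer", config = "list"))

setValidity("GRNFit", function(object) {
  msg <- character()
  if (nrow(object@history) != object@iterations + 1L)
    msg <- c(msg, "history must have iterations + 1 rows (incl. initialization)")
  if (!all(is.finite(object@theta)))
    msg <- c(msg, "theta must be finite")
  if (length(msg)) msg else TRUE
})
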