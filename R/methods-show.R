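# show() and accessor methods

#' @rdname QuadratureRule-class
#' @export
setMethod("quadPoints", "QuadratureRule", function(object) object@points)

#' @rdname QuadratureRule-class
#' @export
setMethod("quadWeights", "QuadratureRule", function(object) object@weights)

setMethod("show", "QuadratureRule", function(object) {
  cat(sprintf("Unscented quadrature rule: dim %d, %d points, kappa = %g\n",
              object@dim, ncol(object@points), object@kappa))
})

#' @rdname GaussianBelief-class
#' @export
setMethod("beliefMean", "GaussianBelief", function(object) object@mean)

#' @rdname GaussianBelief-class
#' @export
setMethod("beliefCov", "GaussianBelief", function(object) object@cov)

setMethod("show", "GaussianBelief", function(object) {
  cat(sprintf("Gaussian belief, dim %d\n", length(object@mean)))
  cat("  mean:", paste(signif(object@mean, 4), collapse = " "), "\n")
  cat(sprintf("  cov trace: %g\n", sum(diag(object@cov))))
})

setMethod("show", "StateSpaceModel", function(object) {
  cat(sprintf(
    "State-space model: state dim %d, obs dim %d, %d parameters%s%s\n",
    object@stateDim, object@obsDim, object@thetaDim,
    if (is.null(object@regressor)) "" else " (linear in theta)",
    if (object@thetaInMeasurement) ", theta in measurement" else ""))
})

#' @rdname FilterTrace-class
#' @export
setMethod("filteredBelief", "FilterTrace", function(object, k) {
  stopifnot(k >= 1L, k <= object@nTime)
  object@steps[[k]]$filtered
})

#' @rdname FilterTrace-class
#' @export
setMethod("predictedBelief", "FilterTrace", function(object, k) {
  stopifnot(k >= 1L, k <= object@nTime)
  object@steps[[k]]$predicted
})

setMethod("show", "FilterTrace", function(object) {
  cat(sprintf("Forward filter trace: K = %d time points, state dim %d\n",
              object@nTime, object@stateDim))
})

#' @rdname SmoothTrace-class
#' @export
setMethod("smoothedMeans", "SmoothTrace", function(object) object@means)

#' @rdname SmoothTrace-class
#' @export
setMethod("smoothedCovs", "SmoothTrace", function(object) object@covs)

#' @rdname SmoothTrace-class
#' @export
setMethod("smootherGains", "SmoothTrace", function(object) object@gains)

setMethod("show", "SmoothTrace", function(object) {
  cat(sprintf("Smoothed state trace: K = %d time points, state dim %d\n",
              object@nTime, object@stateDim))
})

setMethod("show", "QStatistics", function(object) {
  cat(sprintf("Q-function sufficient statistics over %d transitions (dim %d)\n",
              object@nTerms, nrow(object@Sxx)))
})

setMethod("show", "SparsePrior", function(object) {
  cat(sprintf("Sparse prior: mode '%s'", object@mode))
  if (object@mode == "rem")
    cat(sprintf(", lambda in [%g, %g]", min(object@lam), max(object@lam)))
  if (object@mode == "rem_w")
    cat(sprintf(", reweight eps = %g", object@epsReweight))
  cat("\n")
})

#' @rdname GRNFit-class
#' @export
setMethod("coefMatrix", "GRNFit", function(object) object@A)

#' @rdname GRNFit-class
#' @export
setMethod("thetaHat", "GRNFit", function(object) object@theta)

#' @rdname GRNFit-class
#' @export
setMethod("emHistory", "GRNFit", function(object) object@history)

setMethod("show", "GRNFit", function(object) {
  cat(sprintf("GRN fit (%s): %d parameters, %d iterations, %s\n",
              object@mode, length(object@theta), object@iterations,
              if (object@converged) "converged" else "not converged"))
  nz <- sum(object@theta != 0)
  cat(sprintf("  nonzero coefficients: %d / %d\n", nz, length(object@theta)))
  if (nrow(object@A) > 0) {
    cat("  coefficient matrix:\n")
    print(signif(object@A, 3))
  }
})
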