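# Support-recovery metrics: RMSE over matrix entries, sparsity factor,
# matched elements, and magnitude-threshold ROC.

#' Entry-wise RMSE between coefficient matrices
#'
#' \eqn{\sqrt{\frac{1}{n^2}\sum_{ij}(A_{ij} - \hat A_{ij})^2}}.
#'
#' @param A true n x n matrix.
#' @param Ahat estimated matrix of the same shape.
#' @return scalar RMSE.
#' @export
coefRMSE <- function(A, Ahat) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  if (!all(dim(A) == dim(Ahat))) stop("A and Ahat must have the same shape")
  sqrt(mean((A - Ahat)^2))
}

#' Binary support of a coefficient matrix
#'
#' Entry 1 where the coefficient magnitude exceeds `zeroTol`, else 0. The
#' default tolerance is essentially exact-zero detection: the thresholding
#' M-step produces literal zeros, so no fuzzy cutoff is needed.
#'
#' @param A coefficient matrix.
#' @param zeroTol magnitudes at or below this count as zero.
#' @return binary matrix of the same shape.
#' @export
supportMatrix <- function(A, zeroTol = 1e-12) {
  (abs(as.matrix(A)) > zeroTol) * 1L
}

#' Sparsity factor
#'
#' Ratio \eqn{\phi_0/\phi} of the number of (near-)zero entries in the
#' estimate to the number of exact zeros in the truth. 1 is ideal; values
#' above 1 flag an over-sparse estimate.
#'
#' @inheritParams coefRMSE
#' @param zeroTol zero tolerance applied to the estimate.
#' @return scalar ratio.
#' @export
sparsityFactor <- function(A, Ahat, zeroTol = 1e-12) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  if (!all(dim(A) == dim(Ahat))) stop("A and Ahat must have the same shape")
  phi <- sum(A == 0)
  if (phi == 0)
    stop("sparsity factor is undefined: the true matrix has no zero entries")
  phi0 <- sum(abs(Ahat) <= zeroTol)
  phi0 / phi
}

#' Number of matched support elements
#'
#' Builds both binary supports and counts the positions where they agree
#' (the zero entries of their difference). Equals n^2 iff the supports are
#' identical.
#'
#' @inheritParams sparsityFactor
#' @return integer in 0..n^2.
#' @export
matchedElements <- function(A, Ahat, zeroTol = 1e-12) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  if (!all(dim(A) == dim(Ahat))) stop("A and Ahat must have the same shape")
  S <- supportMatrix(A, 0)
  Sh <- supportMatrix(Ahat, zeroTol)
  sum(S - Sh == 0L)
}

#' ROC curve of link recovery by magnitude thresholding
#'
#' Sweeps a threshold tau over the sorted estimate magnitudes; at each tau a
#' link is predicted where \eqn{|\hat A_{ij}| > \tau}. True/false positive
#' rates are counted against the support of the true matrix over all n^2
#' positions (diagonal included). The returned curve includes the (0, 0) and
#' (1, 1) endpoints and is sorted by FPR.
#'
#' @inheritParams coefRMSE
#' @return data.frame with columns `threshold`, `FPR`, `TPR`, `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
rocCurve <- function(A, Ahat) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  if (!all(dim(A) == dim(Ahat))) stop("A and Ahat must have the same shape")
  truth <- A != 0
  nPos <- sum(truth)
  nNeg <- sum(!truth)
  if (nPos == 0)
    stop("ROC is undefined: the true matrix has no links (empty positive class)")
  if (nNeg == 0)
    stop("ROC is undefined: the true matrix has no non-links (empty negative class)")
  mag <- abs(Ahat)
  # -Inf closes the sweep with the everything-predicted (1, 1) endpoint
  taus <- c(Inf, sort(unique(as.vector(mag)), decreasing = TRUE), -Inf)
  rows <- lapply(taus, function(tau) {
    pred <- mag > tau
    TP <- sum(pred & truth); FP <- sum(pred & !truth)
    FN <- nPos - TP; TN <- nNeg - FP
    data.frame(threshold = tau, FPR = FP / nNeg, TPR = TP / nPos,
               TP = TP, FP = FP, TN = TN, FN = FN)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$FPR, out$TPR), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [rocCurve()].
#'
#' @inheritParams coefRMSE
#' @return scalar in 0..1.
#' @export
aucROC <- function(A, Ahat) {
  roc <- rocCurve(A, Ahat)
  sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) + utils::tail(roc$TPR, -1)) / 2)
}

#' Full metrics report
#'
#' Convenience bundle of all support-recovery metrics for one estimate.
#'
#' @inheritParams sparsityFactor
#' @return list with `rmse`, `sparsityFactor`, `matchedElements`, `auc`,
#'   `counts` (TP/FP/TN/FN at the exact-zero threshold), and `roc` (the
#'   curve data.frame).
#' @export
metricsReport <- function(A, Ahat, zeroTol = 1e-12) {
  truth <- as.matrix(A) != 0
  pred <- abs(as.matrix(Ahat)) > zeroTol
  list(rmse = coefRMSE(A, Ahat),
       sparsityFactor = sparsityFactor(A, Ahat, zeroTol),
       matchedElements = matchedElements(A, Ahat, zeroTol),
       auc = aucROC(A, Ahat),
       counts = c(TP = sum(pred & truth), FP = sum(pred & !truth),
                  TN = sum(!pred & !truth), FN = sum(!pred & truth)),
       roc = rocCurve(A, Ahat))
}
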