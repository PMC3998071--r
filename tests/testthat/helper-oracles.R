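# Independent oracles used across the suite.  All are closed-form or
# classical-textbook implementations, deliberately separate from the package
# code paths they check.

# --- Gauss-Hermite quadrature for standard-normal expectations (1-D) ------
# pracma::gaussHermite gives nodes/weights for integral f(x) exp(-x^2) dx;
# substitute x = sqrt(2) t to get E_{N(0,1)}.
ghStandardNormal <- function(nNodes = 20) {
  gh <- pracma::gaussHermite(nNodes)
  list(nodes = sqrt(2) * gh$x, weights = gh$w / sqrt(pi))
}

ghExpect1d <- function(g, mean = 0, sd = 1, nNodes = 20) {
  gh <- ghStandardNormal(nNodes)
  sum(gh$weights * vapply(gh$nodes, function(t) g(mean + sd * t), numeric(1)))
}

# tensor-product GH expectation over a 2-D Gaussian N(mu, Sigma)
ghExpect2d <- function(g, mu, Sigma, nNodes = 20) {
  gh <- ghStandardNormal(nNodes)
  S <- t(chol((Sigma + t(Sigma)) / 2))
  total <- 0
  for (i in seq_along(gh$nodes)) {
    for (j in seq_along(gh$nodes)) {
      z <- mu + S %*% c(gh$nodes[i], gh$nodes[j])
      total <- total + gh$weights[i] * gh$weights[j] * g(z)
    }
  }
  total
}

# --- closed-form Kalman filter / RTS smoother oracle ----------------------
# Same conventions as forwardPass: step 1 holds the initial belief with no
# update; steps 2..K alternate predict/update.  Model: x' = F x + u,
# y = H x + v.
kalmanForward <- function(Y, F, H, U, R, m0, P0) {
  K <- nrow(Y)
  n <- length(m0)
  predM <- matrix(NA_real_, K, n); predP <- vector("list", K)
  filtM <- matrix(NA_real_, K, n); filtP <- vector("list", K)
  filtM[1, ] <- m0; filtP[[1]] <- P0
  predM[1, ] <- m0; predP[[1]] <- P0
  for (k in 2:K) {
    mp <- drop(F %*% filtM[k - 1, ])
    Pp <- F %*% filtP[[k - 1]] %*% t(F) + U
    S <- H %*% Pp %*% t(H) + R
    G <- Pp %*% t(H) %*% solve(S)
    predM[k, ] <- mp; predP[[k]] <- Pp
    filtM[k, ] <- mp + drop(G %*% (Y[k, ] - H %*% mp))
    filtP[[k]] <- Pp - G %*% H %*% Pp
  }
  list(predM = predM, predP = predP, filtM = filtM, filtP = filtP)
}

rtsBackward <- function(kf, F) {
  K <- nrow(kf$filtM)
  n <- ncol(kf$filtM)
  sm <- matrix(NA_real_, K, n); sP <- vector("list", K)
  D <- vector("list", K - 1)
  lag1 <- vector("list", K - 1)  # Cov(x_k, x_{k+1} | all data)
  sm[K, ] <- kf$filtM[K, ]; sP[[K]] <- kf$filtP[[K]]
  for (k in seq(K - 1, 1)) {
    Dk <- kf$filtP[[k]] %*% t(F) %*% solve(kf$predP[[k + 1]])
    sm[k, ] <- kf$filtM[k, ] + drop(Dk %*% (sm[k + 1, ] - kf$predM[k + 1, ]))
    sP[[k]] <- kf$filtP[[k]] +
      Dk %*% (sP[[k + 1]] - kf$predP[[k + 1]]) %*% t(Dk)
    D[[k]] <- Dk
    lag1[[k]] <- Dk %*% sP[[k + 1]]
  }
  list(m = sm, P = sP, D = D, lag1 = lag1)
}

# --- model builders -------------------------------------------------------
# linear-in-theta state-space model x' = F x + u, y = x + v, with F packed
# row-major (regressor = identity) so the quadratic E/M path applies.
linearModel <- function(n) {
  stateSpaceModel(
    transition = function(x, theta) drop(unpackTheta(theta, n) %*% x),
    measurement = function(x, theta) x,
    stateDim = n, obsDim = n, thetaDim = n * n,
    regressor = function(x) x)
}

# random matrix scaled to a given spectral radius
randomStableMatrix <- function(n, radius = 0.8) {
  F <- matrix(rnorm(n * n), n, n)
  F * radius / max(Mod(eigen(F, only.values = TRUE)$values))
}

randomPSD <- function(n, scale = 1) {
  M <- matrix(rnorm(n * n), n, n)
  scale * (crossprod(M) / n + 0.1 * diag(n))
}

belief <- function(mean, cov) new("GaussianBelief", mean = mean, cov = cov)

# simulate a linear-Gaussian trajectory (independent of simulateGRN)
simulateLinear <- function(F, K, U, R, x0) {
  n <- length(x0)
  Su <- t(chol(U)); Sr <- t(chol(R))
  X <- matrix(0, K, n); X[1, ] <- x0
  for (k in 2:K) X[k, ] <- drop(F %*% X[k - 1, ]) + drop(Su %*% rnorm(n))
  Y <- X + t(Sr %*% matrix(rnorm(n * K), n, K))
  Y
}
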