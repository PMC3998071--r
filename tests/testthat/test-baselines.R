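test_that("the L1 trajectory fit with lambda = 0 solves the normal equations", {
  A <- fixtureA("four_gene")
  # noiseless, consistent data generated along the printed reference
  # trajectory: y_k = A g(xhat_{k-1}) with xhat propagated by g alone.
  # K is kept small: the g-only propagation contracts to the sigmoid fixed
  # point, so long horizons make the design numerically rank deficient.
  K <- 6; n <- 4
  x1 <- c(2, -3, 1.5, -0.8)
  Xhat <- matrix(0, K, n)
  Xhat[1, ] <- x1
  for (k in 1:(K - 1)) Xhat[k + 1, ] <- sigmoidLink(Xhat[k, ])
  Y <- matrix(0, K, n)
  Y[1, ] <- x1
  for (k in 2:K) Y[k, ] <- drop(A %*% sigmoidLink(Xhat[k - 1, ]))
  fit <- l1TrajectoryFit(Y, x1 = x1, lam = 0)
  # oracle: Gram-matrix solve of the same design (its own accuracy is
  # limited by the squared condition number, hence the looser tolerance)
  G <- sigmoidLink(Xhat[1:(K - 1), ])
  Astar <- t(solve(crossprod(G), crossprod(G, Y[2:K, ])))
  expect_equal(unname(coefMatrix(fit)), Astar, tolerance = 1e-5)
  # on consistent noiseless data the fit recovers the generator exactly
  expect_equal(unname(coefMatrix(fit)), unname(A), tolerance = 1e-8)
})

test_that("an overwhelming L1 penalty empties the trajectory fit", {
  A <- fixtureA("four_gene")
  se <- simulateGRN(A, K = 15, U = 0.01, R = 0.01, seed = 51)
  fit <- l1TrajectoryFit(expressionMatrix(se), lam = 1e7)
  expect_identical(thetaHat(fit), rep(0, 16))
})

test_that("the trajectory fit engine agrees with EM-mode statistics algebra", {
  # lambda = 0 reduces to least squares, which the shared M-step solves in
  # normal-equations form on equivalent sufficient statistics
  set.seed(52)
  K <- 5; n <- 3
  Y <- matrix(rnorm(K * n), K, n)
  x1 <- rnorm(n, sd = 3)
  fit <- l1TrajectoryFit(Y, x1 = x1, lam = 0)
  Xhat <- matrix(0, K, n)
  Xhat[1, ] <- x1
  for (k in 1:(K - 1)) Xhat[k + 1, ] <- sigmoidLink(Xhat[k, ])
  G <- sigmoidLink(Xhat[1:(K - 1), , drop = FALSE])
  st <- new("QStatistics",
            Sxx = crossprod(Y[2:K, , drop = FALSE]),
            Sxg = crossprod(Y[2:K, , drop = FALSE], G),
            Sgg = crossprod(G), Uinv = diag(n), const = 0,
            nTerms = as.integer(K - 1))
  ms <- mStep(st, sparsePrior("em"), rep(0, n * n))
  expect_equal(thetaHat(fit), ms$theta, tolerance = 1e-6)
})

test_that("reweighted and A-propagated variants run and stay deterministic", {
  A <- fixtureA("four_gene")
  se <- simulateGRN(A, K = 20, U = 0.01, R = 0.01, seed = 53)
  Y <- expressionMatrix(se)
  f1 <- l1TrajectoryFit(Y, lam = 0.5, reweighted = TRUE)
  f2 <- l1TrajectoryFit(Y, lam = 0.5, reweighted = TRUE)
  expect_identical(thetaHat(f1), thetaHat(f2))
  f3 <- l1TrajectoryFit(Y, lam = 0.5, propagateWithA = TRUE)
  expect_true(all(is.finite(thetaHat(f3))))
})

test_that("a single BPDN-DF step without dynamics reduces to the prox closed form", {
  # two time points, identity-like measurement of the full augmented state:
  # minimizing ||z - f||^2 + ||lam o z||_1 + data term is checked against the
  # engine on a hand-built separable case instead through the public API:
  # with y2 matching the propagated state exactly and zero rates, the step
  # returns the propagation fixed point.
  n <- 2
  theta0 <- packTheta(matrix(c(0.5, 0, 0, -0.5), 2, 2, byrow = TRUE))
  x1 <- c(0.3, -0.2)
  f2 <- grnTransition(x1, unpackTheta(theta0, n))
  Y <- rbind(x1, f2)
  fit <- bpdnDF(Y, lam = 0, theta0 = theta0)
  expect_equal(thetaHat(fit), theta0, tolerance = 1e-6)
})

test_that("BPDN-DF sparsifies only the parameter part", {
  A <- fixtureA("four_gene")
  se <- simulateGRN(A, K = 10, U = 0.01, R = 0.01, seed = 54)
  Y <- expressionMatrix(se)
  # enormous parameter rates force theta to zero at every step
  fit <- bpdnDF(Y, lam = 1e8, theta0 = rnorm(16))
  expect_identical(thetaHat(fit), rep(0, 16))
  # rates on the state part must be zero
  expect_error(bpdnDF(Y, lam = c(rep(1, 4), rep(0.1, 16))), "state-part")
  # default run is deterministic and finite
  f1 <- bpdnDF(Y, theta0 = rep(0.1, 16))
  f2 <- bpdnDF(Y, theta0 = rep(0.1, 16))
  expect_identical(thetaHat(f1), thetaHat(f2))
})

test_that("the per-step BPDN-DF objective never increases along inner iterations", {
  # convexity check on one assembled step objective via the engine trace:
  # run the engine twice, once to convergence and once truncated; the
  # truncated objective cannot be below the converged one by more than
  # numerical noise
  set.seed(55)
  n <- 2; m <- 4; d <- n + m
  fPrev <- rnorm(d)
  yk <- rnorm(n)
  lam <- c(rep(0, n), rep(0.1, m))
  valueFn <- function(v) sum((yk - v[1:n])^2) + sum((v - fPrev)^2)
  gradFn <- function(v) {
    g <- 2 * (v - fPrev)
    g[1:n] <- g[1:n] - 2 * (yk - v[1:n])
    g
  }
  full <- iterativeThresholding(valueFn, gradFn, lam / 2, fPrev, tol = 1e-12)
  short <- iterativeThresholding(valueFn, gradFn, lam / 2, fPrev,
                                 tol = 1e-12, maxIter = 3)
  expect_gte(short$objective, full$objective - 1e-10)
})
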