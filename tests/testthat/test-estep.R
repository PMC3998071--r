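grnTrace <- function(A, K, noise = 0.01, seed = 7, P0 = 0.5) {
  n <- nrow(A)
  se <- simulateGRN(A, K = K, U = noise, R = noise, seed = seed)
  Y <- expressionMatrix(se)
  model <- grnModel(n)
  theta <- packTheta(A)
  fwd <- forwardPass(Y, model, theta, diag(noise, n), diag(noise, n),
                     belief(Y[1, ], diag(P0, n)), utRule(n))
  list(trace = backwardPass(fwd, model, theta, utRule(n)), model = model,
       U = diag(noise, n), n = n)
}

test_that("point-mass joints reduce the statistics to plug-in sums", {
  n <- 2
  means <- matrix(c(0.3, -0.4, 1.1, 0.2, -0.5, 0.8), 3, n, byrow = TRUE)
  zero <- matrix(0, n, n)
  trace <- new("SmoothTrace", means = means,
               covs = list(zero, zero, zero),
               gains = list(zero, zero), cross = list(zero, zero),
               nTime = 3L, stateDim = 2L)
  st <- qStatistics(trace, grnModel(n), diag(0.01, n), utRule(2 * n))
  Sxx <- Sxg <- Sgg <- matrix(0, n, n)
  for (k in 1:2) {
    g <- sigmoidLink(means[k, ])
    Sxx <- Sxx + tcrossprod(means[k + 1, ])
    Sxg <- Sxg + means[k + 1, ] %*% t(g)
    Sgg <- Sgg + tcrossprod(g)
  }
  expect_equal(st@Sxx, Sxx, tolerance = 1e-12)
  expect_equal(st@Sxg, Sxg, tolerance = 1e-12)
  expect_equal(st@Sgg, Sgg, tolerance = 1e-12)
})

test_that("K = 2 scalar GRN statistics match a dense Gauss-Hermite oracle", {
  A <- matrix(1.5, 1, 1)
  fx <- grnTrace(A, K = 2, P0 = 0.01)
  st <- qStatistics(fx$trace, fx$model, fx$U, utRule(2))
  J <- pairwiseJoint(fx$trace, 1)
  mu <- beliefMean(J); Sg <- beliefCov(J)
  oXX <- ghExpect2d(function(z) z[2]^2, mu, Sg)
  oXG <- ghExpect2d(function(z) z[2] * sigmoidLink(z[1]), mu, Sg)
  oGG <- ghExpect2d(function(z) sigmoidLink(z[1])^2, mu, Sg)
  expect_equal(st@Sxx[1, 1], oXX, tolerance = 1e-6)
  expect_equal(st@Sxg[1, 1], oXG, tolerance = 1e-6)
  expect_equal(st@Sgg[1, 1], oGG, tolerance = 1e-6)
})

test_that("statistics are fixed by the trace, independent of the theta evaluated", {
  A <- matrix(c(1, -2, 0.5, 0), 2, 2, byrow = TRUE)
  fx <- grnTrace(A, K = 4)
  s1 <- qStatistics(fx$trace, fx$model, fx$U, utRule(4))
  s2 <- qStatistics(fx$trace, fx$model, fx$U, utRule(4))
  expect_identical(s1@Sxx, s2@Sxx)
  expect_identical(s1@Sxg, s2@Sxg)
  set.seed(2)
  th <- rnorm(4)
  # same quadratic whatever theta it is evaluated at
  expect_equal(qValue(th, s1), qValue(th, s2))
})

test_that("qValue agrees with direct quadrature of the transition integrals", {
  A <- matrix(c(1, -2, 0.5, 0), 2, 2, byrow = TRUE)
  fx <- grnTrace(A, K = 3, seed = 11)
  st <- qStatistics(fx$trace, fx$model, fx$U, utRule(4))
  set.seed(4)
  for (i in 1:3) {
    th <- rnorm(4)
    expect_equal(qValue(th, st),
                 qValueDirect(th, fx$trace, fx$model, fx$U, utRule(4)),
                 tolerance = 1e-8)
  }
  # value at the origin is the pure state term
  expect_equal(qValue(rep(0, 4), st), sum(st@Uinv * st@Sxx),
               tolerance = 1e-12)
})

test_that("qValue is an exact quadratic along any parameter line", {
  A <- fixtureA("four_gene")
  fx <- grnTrace(A, K = 6, seed = 13)
  st <- qStatistics(fx$trace, fx$model, fx$U, utRule(8))
  set.seed(6)
  th0 <- rnorm(16); d <- rnorm(16)
  f <- function(t) qValue(th0 + t * d, st)
  # fit a parabola through t = 0, 1, 2 and predict t = 3.5
  y <- c(f(0), f(1), f(2))
  cc <- solve(rbind(c(1, 0, 0), c(1, 1, 1), c(1, 2, 4)), y)
  tnew <- 3.5
  expect_equal(drop(c(1, tnew, tnew^2) %*% cc), f(tnew),
               tolerance = 1e-10 * max(1, abs(f(tnew))))
})

test_that("the analytic gradient matches finite differences and vanishes at A*", {
  A <- fixtureA("four_gene")
  fx <- grnTrace(A, K = 6, seed = 17)
  st <- qStatistics(fx$trace, fx$model, fx$U, utRule(8))
  set.seed(8)
  h <- 1e-6
  for (i in 1:20) {
    th <- rnorm(16)
    g <- qGradient(th, st)
    gn <- vapply(seq_along(th), function(j) {
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (qValue(tp, st) - qValue(tm, st)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gn)) / max(abs(gn), 1), 1e-5)
    # directional derivative along a random direction
    d <- rnorm(16); d <- d / sqrt(sum(d^2))
    dd <- (qValue(th + h * d, st) - qValue(th - h * d, st)) / (2 * h)
    expect_equal(sum(g * d), dd, tolerance = 1e-4 * max(1, abs(dd)))
  }
  # first-order condition at the unconstrained minimizer
  Astar <- t(solve(st@Sgg, t(st@Sxg)))
  expect_lt(max(abs(qGradient(packTheta(Astar), st))), 1e-8)
  # numeric fallback agrees with the analytic path
  th <- rnorm(4)
  A2 <- matrix(c(1, -2, 0.5, 0), 2, 2, byrow = TRUE)
  fx2 <- grnTrace(A2, K = 3, seed = 11)
  st2 <- qStatistics(fx2$trace, fx2$model, fx2$U, utRule(4))
  expect_equal(qGradient(th, st2),
               qGradientNumeric(th, fx2$trace, fx2$model, fx2$U, utRule(4)),
               tolerance = 1e-5)
})

test_that("qStatistics rejects models without a regressor and bad rules", {
  nl <- stateSpaceModel(function(x, theta) sin(theta[1] * x),
                        function(x, theta) x, 1, 1, 1)
  A <- matrix(0.5, 1, 1)
  fx <- grnTrace(A, K = 3)
  expect_error(qStatistics(fx$trace, nl, fx$U, utRule(2)), "linear in theta")
  expect_error(qStatistics(fx$trace, fx$model, fx$U, utRule(3)), "2n")
})
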