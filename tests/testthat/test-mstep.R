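test_that("softThreshold shrinks toward zero with exact zeros", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  expect_equal(softThreshold(c(2, -3, 0.1), c(1, 1, 1)), c(1, -2, 0))
  expect_error(softThreshold(1, -0.1), "nonnegative")
})

test_that("softThreshold matches the grid-search prox minimizer", {
  set.seed(21)
  grid <- seq(-6, 6, by = 1e-4)
  for (i in 1:200) {
    u <- runif(1, -3, 3)
    a <- runif(1, 0, 2)
    obj <- 0.5 * (grid - u)^2 + a * abs(grid)
    zstar <- grid[which.min(obj)]
    expect_lt(abs(softThreshold(u, a) - zstar), 1.5e-4)
  }
})

test_that("bbStep is the least-squares secant ratio with a safeguard", {
  expect_equal(bbStep(1, 2), 2)
  s <- c(0.3, -0.2, 1)
  expect_equal(bbStep(s, s), 1)
  expect_equal(bbStep(c(1, 0), c(-2, 0)), 1)   # s'r < 0 -> safeguard
  expect_equal(bbStep(c(0, 0), c(1, 1)), 1)    # s = 0 -> safeguard
  expect_equal(bbStep(c(1, 2), c(2, 4)), 2)
  expect_error(bbStep(1:2, 1:3), "same length")
})

test_that("unpenalized thresholding converges to the quadratic minimizer", {
  set.seed(22)
  for (i in 1:3) {
    n <- 6
    M <- matrix(rnorm(n * n), n)
    H <- crossprod(M) / n + diag(n)     # SPD Hessian
    b <- rnorm(n)
    valueFn <- function(th) 0.5 * sum(th * (H %*% th)) - sum(b * th)
    gradFn <- function(th) drop(H %*% th) - b
    thStar <- solve(H, b)
    res <- iterativeThresholding(valueFn, gradFn, rep(0, n), rnorm(n),
                                 tol = 1e-14, maxIter = 5000)
    expect_lt(sqrt(sum((res$theta - thStar)^2)), 1e-6)
    expect_lte(res$objective, valueFn(rnorm(n)) + 1)  # finite final J
  }
})

test_that("overwhelming penalties produce the exact zero vector", {
  valueFn <- function(th) sum((th - 5)^2)
  gradFn <- function(th) 2 * (th - 5)
  res <- iterativeThresholding(valueFn, gradFn, rep(1e6, 3), c(5, -5, 2))
  expect_identical(res$theta, c(0, 0, 0))
})

test_that("a separable quadratic is solved by one prox step from its center", {
  set.seed(23)
  u <- rnorm(5)
  lam <- runif(5, 0, 1)
  valueFn <- function(th) 0.5 * sum((th - u)^2)
  gradFn <- function(th) th - u
  res <- iterativeThresholding(valueFn, gradFn, lam, u, tol = 1e-10)
  # alpha_0 = 1, gradient zero at u: first iterate is the prox at threshold 2*lam
  expect_equal(res$theta, softThreshold(u, 2 * lam), tolerance = 1e-10)
  # cross-check one coordinate against a fine grid search on the full objective
  grid <- seq(-4, 4, by = 1e-4)
  for (j in c(1, 3)) {
    obj <- 0.5 * (grid - u[j])^2 + 2 * lam[j] * abs(grid)
    expect_lt(abs(res$theta[j] - grid[which.min(obj)]), 1.5e-4)
  }
})

test_that("reweightLambda implements 1/(|theta| + eps)", {
  expect_equal(reweightLambda(0, 0.01), 100)
  expect_equal(reweightLambda(0.99, 0.01), 1)
  th <- c(-0.5, 0.5, 2)
  expect_equal(reweightLambda(th), reweightLambda(-th))
  expect_error(reweightLambda(1, eps = 0), "positive")
})

test_that("EM-mode mStep reproduces the normal-equations solution", {
  A <- fixtureA("four_gene")
  se <- simulateGRN(A, K = 10, U = 0.01, R = 0.01, seed = 31)
  Y <- expressionMatrix(se)
  model <- grnModel(4)
  theta <- packTheta(A)
  fwd <- forwardPass(Y, model, theta, diag(0.01, 4), diag(0.01, 4),
                     belief(Y[1, ], diag(0.5, 4)), utRule(4))
  smo <- backwardPass(fwd, model, theta, utRule(4))
  st <- qStatistics(smo, model, diag(0.01, 4), utRule(8))
  res <- mStep(st, sparsePrior("em"), rnorm(16))
  expect_equal(unpackTheta(res$theta, 4), st@Sxg %*% solve(st@Sgg),
               tolerance = 1e-8)
  # the rem path with lambda = 0 lands on the same minimizer
  res0 <- mStep(st, sparsePrior("rem", lam = 0), rep(0, 16),
                innerTol = 1e-12, innerMaxIter = 5000)
  expect_equal(res0$theta, res$theta, tolerance = 1e-5)
})

test_that("re-weighted mStep zeros out small coordinates of a quadratic", {
  # separable 2-D quadratic with one dominant and one weak coordinate
  H <- diag(c(2, 2))
  b <- c(8, 0.04)   # minimizers 4 and 0.02
  st <- NULL
  valueFn <- function(th) 0.5 * sum(th * (H %*% th)) - sum(b * th)
  gradFn <- function(th) drop(H %*% th) - b
  lam <- rep(1, 2)
  theta <- c(0, 0)
  for (round in 1:10) {
    res <- iterativeThresholding(valueFn, gradFn, lam, theta, tol = 1e-10)
    if (round > 1 && max(abs(res$theta - theta)) < 1e-8) { theta <- res$theta; break }
    theta <- res$theta
    lam <- reweightLambda(theta, 0.01)
  }
  expect_equal(theta[2], 0)
  expect_gt(theta[1], 3)
  # grid-search confirmation for the surviving coordinate at its final rate
  grid <- seq(0, 5, by = 1e-4)
  obj <- 0.5 * 2 * grid^2 - 8 * grid + 2 * lam[1] * abs(grid)
  expect_lt(abs(theta[1] - grid[which.min(obj)]), 1e-3)
})

test_that("mStep is deterministic across repeated calls", {
  A <- fixtureA("four_gene")
  se <- simulateGRN(A, K = 8, U = 0.01, R = 0.01, seed = 33)
  Y <- expressionMatrix(se)
  model <- grnModel(4)
  theta <- packTheta(A)
  fwd <- forwardPass(Y, model, theta, diag(0.01, 4), diag(0.01, 4),
                     belief(Y[1, ], diag(0.5, 4)), utRule(4))
  smo <- backwardPass(fwd, model, theta, utRule(4))
  st <- qStatistics(smo, model, diag(0.01, 4), utRule(8))
  set.seed(1); th0 <- rnorm(16)
  r1 <- mStep(st, sparsePrior("rem_w"), th0)
  r2 <- mStep(st, sparsePrior("rem_w"), th0)
  expect_identical(r1$theta, r2$theta)
  expect_true(any(r1$theta == 0))  # shrinkage active -> literal zeros
})
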