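test_that("full shrinkage: l1 at the bound gives the zero vector", {
  set.seed(1)
  X <- matrix(rnorm(40 * 10), 40)
  y <- balancedLabels(40)
  bound <- 2 * max(abs(crossprod(X, y) / nrow(X)))
  w <- l1l2Solve(X, y, l1 = bound, mu = 0.01)
  expect_equal(w, rep(0, 10), ignore_attr = TRUE)
  w2 <- l1l2Solve(X, y, l1 = bound * 1.5, mu = 0)
  expect_equal(w2, rep(0, 10), ignore_attr = TRUE)
})

test_that("penalty-free limit recovers ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  w <- l1l2Solve(X, y, l1 = 0, mu = 0, tol = 1e-10)
  ols <- qr.solve(X, y)
  expect_equal(w, unname(ols), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("solver matches the independent convex oracle on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  for (i in 1:40) {
    n <- sample(10:40, 1); p <- sample(3:60, 1)
    X <- matrix(rnorm(n * p), n)
    y <- balancedLabels(n)[sample(n)]
    l1 <- runif(1, 0.02, 0.5); mu <- runif(1, 0, 0.3)
    w <- l1l2Solve(X, y, l1, mu, tol = 1e-8)
    wo <- glmnetOracle(X, y, l1, mu)
    obj <- GOwise:::l1l2Objective(X, y, w, l1, mu)
    objO <- GOwise:::l1l2Objective(X, y, wo, l1, mu)
    expect_lte(obj, objO + 1e-6)
    expect_lte(attr(w, "kkt"), 1e-8 * 1.01)
  }
})

test_that("support size is non-increasing in the l1 weight", {
  set.seed(4)
  X <- matrix(rnorm(30 * 20), 30)
  y <- balancedLabels(30)
  grid <- GOwise:::geomSeq(1e-3, 1, 12) * GOwise:::l1Max(X, y)
  sizes <- vapply(grid, function(l1)
    sum(l1l2Solve(X, y, l1, mu = 0.01) != 0), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("larger mu draws duplicated informative columns in together", {
  # operational check of the correlation parameter: with a duplicated
  # informative column, high mu should co-select both copies more often
  set.seed(5)
  co <- function(mu) {
    hits <- 0L
    for (s in 1:15) {
      n <- 40
      y <- balancedLabels(n)[sample(n)]
      signal <- y * 1.2 + rnorm(n, 0, 0.5)
      X <- cbind(signal, signal + rnorm(n, 0, 0.02),
                 matrix(rnorm(n * 10), n))
      X <- scale(X)
      l1 <- 0.3 * GOwise:::l1Max(X, y)
      w <- l1l2Solve(X, y, l1, mu = mu)
      if (w[1] != 0 && w[2] != 0) hits <- hits + 1L
    }
    hits
  }
  expect_gt(co(0.5), co(1e-4))
})

test_that("RLS solves the regularized normal equations", {
  set.seed(6)
  # square invertible, lam = 0: exact interpolation
  X <- matrix(rnorm(16), 4)
  y <- c(1, -1, 1, -1)
  w <- rlsSolve(X, y, lam = 0)
  expect_equal(as.numeric(X %*% w), y, tolerance = 1e-8)

  # closed-form oracle on a 3x2 system at lam = 0.5
  X2 <- matrix(c(1, 2, 3, 0.5, -1, 2), 3)
  y2 <- c(1, -1, 1)
  w2 <- rlsSolve(X2, y2, lam = 0.5)
  oracle <- solve(crossprod(X2) + 3 * 0.5 * diag(2), crossprod(X2, y2))
  expect_equal(w2, as.numeric(oracle), tolerance = 1e-10)

  # ridge limit: norm shrinks monotonically to 0
  norms <- vapply(c(0.1, 1, 10, 100, 1e4), function(l)
    sqrt(sum(rlsSolve(X2, y2, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 1e-3)

  # rank-deficient: pseudo-inverse returns the minimum-norm solution
  X3 <- cbind(1:4, 1:4)
  w3 <- rlsSolve(X3, c(2, 4, 6, 8), lam = 0)
  expect_equal(w3, c(1, 1), tolerance = 1e-8)
})

test_that("sign classification breaks ties to +1 and recounts errors", {
  X <- matrix(rnorm(20), 5)
  expect_equal(classifyLabels(rep(0, 4), X), rep(1, 5))
  # separable 1-D data with a correct-sign weight: zero errors
  x1 <- matrix(c(-2, -1, 1, 2), 4)
  expect_equal(classifyLabels(2, x1), c(-1, -1, 1, 1))
  # error equals the recounted sign mismatches
  set.seed(7)
  w <- rnorm(4); Xr <- matrix(rnorm(40), 10); yr <- balancedLabels(10)
  pred <- classifyLabels(w, Xr)
  expect_equal(GOwise:::errorRate(pred, yr),
               sum(sign(Xr %*% w + 1e-300) != yr) / 10)
})
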