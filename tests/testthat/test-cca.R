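test_that("univariate CCA reduces to the absolute Pearson correlation", {
  set.seed(31)
  x <- matrix(rnorm(40), dimnames = list(paste0("s", 1:40), "x"))
  y <- matrix(0.6 * x + rnorm(40, sd = 0.5),
              dimnames = list(paste0("s", 1:40), "y"))
  pd <- pairedOmics(x, y)
  fit <- fitCCA(pd, 1)
  expect_equal(latentCor(fit)[1], abs(cor(x, y)[1, 1]), tolerance = 1e-12)
})

test_that("canonical correlations match the generalized-eigen oracle", {
  pd <- randomPaired(50, 3, 2, seed = 33)
  fit <- fitCCA(pd, 2)
  X <- xMatrix(pd); Y <- yMatrix(pd)
  Sxx <- cov(X); Syy <- cov(Y); Sxy <- cov(X, Y)
  ev <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy),
              only.values = TRUE)$values
  ev <- sqrt(pmax(Re(ev), 0))
  expect_lt(max(abs(latentCor(fit) - ev[1:2])), 1e-8)
})

test_that("CCA is invariant under invertible linear maps of one block", {
  pd <- randomPaired(40, 3, 3, seed = 35)
  B <- matrix(c(2, 0.5, 0, -1, 1, 0.3, 0.2, 0, 1), 3, 3)
  Y2 <- xMatrix(pd) %*% B
  colnames(Y2) <- paste0("t", 1:3)
  pd2 <- pairedOmics(xMatrix(pd), Y2)
  fit <- fitCCA(pd2, 3)
  expect_equal(unname(latentCor(fit)), rep(1, 3), tolerance = 1e-8)
})

test_that("CCA contracts hold: unit variates, consistency, orthogonality", {
  pd <- randomPaired(60, 4, 3, seed = 37)
  fit <- fitCCA(pd, 3)
  U <- xVariates(fit); V <- yVariates(fit)
  expect_equal(unname(apply(U, 2, var)), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(apply(V, 2, var)), rep(1, 3), tolerance = 1e-6)
  ## reported rho equals the correlation of the returned variates
  expect_equal(unname(latentCor(fit)),
               unname(sapply(1:3, function(l) cor(U[, l], V[, l]))),
               tolerance = 1e-10)
  ## nonincreasing, in [0, 1]
  expect_true(all(diff(latentCor(fit)) <= 1e-12))
  expect_true(all(latentCor(fit) >= 0 & latentCor(fit) <= 1))
  ## successive pairs uncorrelated with previous ones
  cu <- cor(U); cv <- cor(V); cuv <- cor(U, V)
  expect_lt(max(abs(cu[upper.tri(cu)]), abs(cv[upper.tri(cv)]),
                abs(cuv[upper.tri(cuv)]), abs(cuv[lower.tri(cuv)])), 1e-6)
})

test_that("singular covariance is refused with a pointer to fitRCCA", {
  pd <- simulatePair(simulationDesign(), seed = 39)   # p = 100 > n = 30
  expect_error(fitCCA(pd, 2), "fitRCCA")
})

test_that("zero regularization reproduces classical CCA", {
  pd <- randomPaired(50, 4, 3, seed = 41)
  f0 <- fitCCA(pd, 3)
  fr <- fitRCCA(pd, 3, 0, 0)
  expect_lt(max(abs(xLoadings(f0) - xLoadings(fr))), 1e-8)
  expect_lt(max(abs(latentCor(f0) - latentCor(fr))), 1e-8)
})

test_that("rCCA handles p, q > n and stays internally consistent", {
  pd <- simulatePair(simulationDesign(), seed = 43)
  fit <- fitRCCA(pd, 3, 0.5, 0.5)
  expect_true(all(is.finite(xLoadings(fit))))
  expect_true(all(is.finite(yLoadings(fit))))
  rho <- latentCor(fit)
  expect_true(all(diff(rho) <= 1e-12))
  expect_true(all(rho >= 0 & rho <= 1))
})

test_that("rCCA loadings vary continuously in lambda", {
  pd <- simulatePair(simulationDesign(), seed = 45)
  f1 <- fitRCCA(pd, 2, 0.5, 0.5)
  f2 <- fitRCCA(pd, 2, 0.501, 0.501)
  expect_lt(max(abs(xLoadings(f1) - xLoadings(f2))) /
            max(abs(xLoadings(f1))), 0.05)
})

test_that("negative regularization is rejected", {
  pd <- randomPaired(30, 4, 3, seed = 47)
  expect_error(fitRCCA(pd, 2, -0.1, 0.5), "nonnegative")
})

test_that("tuning returns the single grid point when there is no choice", {
  pd <- randomPaired(30, 5, 4, seed = 49)
  tn <- tuneRCCA(pd, grid = 0.25, nFolds = 3, seed = 1)
  expect_equal(tn$lambda1, 0.25)
  expect_equal(tn$lambda2, 0.25)
})

test_that("tuning equals a brute-force CV recomputation and is deterministic", {
  pd <- randomPaired(24, 30, 20, seed = 51)   # p > n: noise-only, needs ridge
  grid <- c(0.01, 1)
  t1 <- tuneRCCA(pd, grid = grid, nFolds = 4, seed = 5)
  t2 <- tuneRCCA(pd, grid = grid, nFolds = 4, seed = 5)
  expect_identical(t1, t2)
  ## brute force: recompute every fold score independently
  set.seed(5)
  folds <- sample(rep(1:4, length.out = 24))
  X <- xMatrix(pd); Y <- yMatrix(pd)
  score <- function(l1, l2) {
    mean(sapply(1:4, function(k) {
      tr <- folds != k
      f <- fitRCCA(pairedOmics(X[tr, ], Y[tr, ]), 1, l1, l2)
      ctrX <- colMeans(X[tr, ]); sclX <- apply(X[tr, ], 2, sd)
      ctrY <- colMeans(Y[tr, ]); sclY <- apply(Y[tr, ], 2, sd)
      u <- sweep(sweep(X[!tr, ], 2, ctrX), 2, sclX, "/") %*% xLoadings(f)
      v <- sweep(sweep(Y[!tr, ], 2, ctrY), 2, sclY, "/") %*% yLoadings(f)
      cor(u, v)[1, 1]
    }))
  }
  pairs <- expand.grid(l1 = grid, l2 = grid)
  bf <- mapply(score, pairs$l1, pairs$l2)
  expect_equal(unname(t1$scores$score), unname(bf), tolerance = 1e-10)
  best <- which.max(bf)
  expect_equal(t1$lambda1, pairs$l1[best])
  expect_equal(t1$lambda2, pairs$l2[best])
})
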