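test_that("PLS on identical blocks gives a perfect first latent pair", {
  pd <- randomPaired(10, 6, 6, seed = 3)
  pdXX <- pairedOmics(xMatrix(pd), xMatrix(pd), standardize = TRUE)
  for (mode in c("regression", "canonical")) {
    fit <- fitPLS(pdXX, 2, mode)
    expect_equal(latentCor(fit)[1], 1, tolerance = 1e-10)
  }
})

test_that("first PLS loading matches the SVD of the cross-product matrix", {
  pd <- randomPaired(10, 6, 4, seed = 5)
  fit <- fitPLS(pd, 1, "regression")
  sv <- svd(crossprod(xMatrix(pd), yMatrix(pd)))
  a <- sv$u[, 1] * sign(sv$u[which.max(abs(sv$u[, 1])), 1])
  expect_lt(max(abs(xLoadings(fit)[, 1] - a)), 1e-8)
  b <- sv$v[, 1] * sign(sv$u[which.max(abs(sv$u[, 1])), 1])
  expect_lt(max(abs(yLoadings(fit)[, 1] - b)), 1e-8)
})

test_that("loadings are unit norm and U variates mutually orthogonal", {
  pd <- randomPaired(20, 8, 5, seed = 7)
  for (mode in c("regression", "canonical")) {
    fit <- fitPLS(pd, 4, mode)
    expect_equal(unname(sqrt(colSums(xLoadings(fit)^2))), rep(1, 4),
                 tolerance = 1e-9)
    expect_equal(unname(sqrt(colSums(yLoadings(fit)^2))), rep(1, 4),
                 tolerance = 1e-9)
    G <- crossprod(xVariates(fit))
    expect_lt(max(abs(G[upper.tri(G)])), 1e-6)
  }
})

test_that("regression-mode deflation reconstructs X exactly at full rank", {
  pd <- randomPaired(12, 6, 4, seed = 9)
  fit <- fitPLS(pd, 6, "regression")   # rank(X) = 6 after centering (n > p)
  recon <- xVariates(fit) %*% t(fit@coefX)
  expect_lt(norm(xMatrix(pd) - recon, "F"), 1e-8)
})

test_that("cor(X^j, U^l) equals sd(U^l) * phi^l_j for standardized data", {
  pd <- randomPaired(15, 7, 5, seed = 11)
  fit <- fitPLS(pd, 3, "canonical")
  cc <- cor(xMatrix(pd), xVariates(fit))
  closed <- sweep(fit@coefX, 2, fit@sdU, "*")
  expect_lt(max(abs(cc - closed)), 1e-8)
  ## canonical mode: same identity on the Y side through V
  cy <- cor(yMatrix(pd), yVariates(fit))
  closedY <- sweep(fit@coefY, 2, fit@sdV, "*")
  expect_lt(max(abs(cy - closedY)), 1e-8)
})

test_that("the latent signal drops sharply after the designed dimensions", {
  ## observable cleanly at n = 500; at n = 30 every residual direction
  ## overfits and keeps the empirical latent correlation inflated
  pd <- simulatePair(simulationDesign(nSamples = 500), seed = 21)
  fit <- fitPLS(pd, 5, "canonical")
  rho <- latentCor(fit)
  expect_true(all(rho[1:3] > 0.9))
  expect_lt(rho[4], rho[3] - 0.2)
  cv <- sapply(1:5, function(l)
    abs(cov(xVariates(fit)[, l], yVariates(fit)[, l])))
  expect_lt(cv[4], 0.5 * cv[3])
})

test_that("fits are deterministic with a fixed sign convention", {
  pd <- randomPaired(20, 10, 6, seed = 13)
  f1 <- fitPLS(pd, 3, "canonical")
  f2 <- fitPLS(pd, 3, "canonical")
  expect_identical(xLoadings(f1), xLoadings(f2))
  tops <- apply(abs(xLoadings(f1)), 2, which.max)
  expect_true(all(xLoadings(f1)[cbind(tops, 1:3)] > 0))
})

test_that("sparse PLS with full keep counts reproduces plain PLS", {
  pd <- randomPaired(20, 8, 5, seed = 15)
  for (mode in c("regression", "canonical")) {
    f  <- fitPLS(pd, 3, mode)
    sf <- fitSPLS(pd, 3, mode, keepX = 8, keepY = 5)
    expect_lt(max(abs(xLoadings(f) - xLoadings(sf))), 1e-8)
    expect_lt(max(abs(yLoadings(f) - yLoadings(sf))), 1e-8)
    expect_lt(max(abs(latentCor(f) - latentCor(sf))), 1e-8)
  }
})

test_that("sparse selection counts are honoured exactly per dimension", {
  pd <- randomPaired(25, 12, 9, seed = 17)
  sf <- fitSPLS(pd, 3, "canonical", keepX = c(4, 7, 12), keepY = c(2, 9, 5))
  expect_equal(unname(colSums(xLoadings(sf) != 0)), c(4, 7, 12))
  expect_equal(unname(colSums(yLoadings(sf) != 0)), c(2, 9, 5))
  expect_error(fitSPLS(pd, 2, "canonical", keepX = 13, keepY = 2), "keepX")
})

test_that("sparse selection recovers the relevant blocks at large n", {
  ## per-dimension counts sized to the designed blocks: each dimension
  ## captures one block pair exactly, no noise id selected anywhere
  pd <- simulatePair(simulationDesign(nSamples = 500), seed = 19)
  sf <- fitSPLS(pd, 3, "canonical", keepX = c(10, 10, 3),
                keepY = c(10, 5, 2))
  sel1 <- selectedVariables(sf, 1)
  expect_setequal(sel1$x, paste0("XA", 1:10))
  expect_setequal(sel1$y, paste0("YA", 1:10))
  selAll <- selectedVariables(sf, 3)
  expect_false(any(isNoiseId(selAll$x)))
  expect_false(any(isNoiseId(selAll$y)))
  expect_setequal(selAll$x, c(paste0("XA", 1:10), paste0("XB", 1:10),
                              paste0("XC", 1:3)))
})

test_that("rank exhaustion and bad arguments raise errors", {
  pd <- randomPaired(10, 3, 3, seed = 23)
  expect_error(fitPLS(pd, 4, "canonical"), "ndim")
  raw <- pairedOmics(xMatrix(pd), yMatrix(pd), standardize = FALSE)
  ## already standardized matrices passed with standardize = FALSE keep the
  ## flag FALSE and are refused by the fitting front ends
  expect_error(fitPLS(raw, 2, "canonical"), "standardized")
})
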