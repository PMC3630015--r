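#' Canonical correlation analysis
#'
#' Classical CCA: finds pairs of unit-variance linear combinations U = Xa,
#' V = Yb maximizing cor(U, V), each pair uncorrelated with the previous
#' ones. Solved through Cholesky whitening of the two covariance matrices
#' and an SVD of the whitened cross-covariance; the canonical correlations
#' are the singular values and equal the empirical correlations of the
#' returned variate pairs.
#'
#' @param data a standardized [PairedOmics-class]; needs well-conditioned
#'   covariance blocks (n comfortably larger than p and q).
#' @param ndim number of canonical pairs, at most min(p, q).
#' @return a [ProjectionFit-class] with method `"cca"`.
#' @examples
#' set.seed(1)
#' pd <- pairedOmics(matrix(rnorm(150), 50, 3), matrix(rnorm(100), 50, 2))
#' latentCor(fitCCA(pd, 2))
#' @seealso [fitRCCA()] for the ridge-regularized version usable when
#'   variables outnumber samples.
#' @export
fitCCA <- function(data, ndim) {
  ccaEngine(data, ndim, lambda1 = 0, lambda2 = 0, tag = "cca")
}

#' Ridge-regularized canonical correlation analysis
#'
#' CCA with `lambda1` and `lambda2` added to the diagonals of the two sample
#' covariance matrices, making the whitening well-posed when p or q exceed
#' n. The reported `rho` values are the singular values of the whitened
#' regularized cross-covariance -- the canonical values the regularized
#' method maximizes; with zero regularization they reduce exactly to the
#' correlations of the variate pairs.
#'
#' @inheritParams fitCCA
#' @param lambda1,lambda2 nonnegative ridge parameters for X and Y.
#' @return a [ProjectionFit-class] with method `"rcca"`.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' latentCor(fitRCCA(pd, 3, 0.889, 0.889))
#' @export
fitRCCA <- function(data, ndim, lambda1, lambda2) {
  if (lambda1 < 0 || lambda2 < 0)
    stop("lambda1 and lambda2 must be nonnegative")
  ccaEngine(data, ndim, lambda1, lambda2, tag = "rcca")
}

ccaEngine <- function(data, ndim, lambda1, lambda2, tag) {
  requireStandardized(data)
  X <- data@X; Y <- data@Y
  p <- ncol(X); q <- ncol(Y)
  ndim <- as.integer(ndim)
  if (ndim < 1L || ndim > min(p, q))
    stop(sprintf("ndim must lie in [1, %d]", min(p, q)))
  Cxx <- stats::cov(X) + diag(lambda1, p)
  Cyy <- stats::cov(Y) + diag(lambda2, q)
  Cxy <- stats::cov(X, Y)
  Rx <- tryCatch(chol(Cxx), error = function(e) NULL)
  Ry <- tryCatch(chol(Cyy), error = function(e) NULL)
  if (is.null(Rx) || is.null(Ry)) {
    if (tag == "cca")
      stop("singular covariance matrix (p or q too large for n); ",
           "use fitRCCA() with positive regularization instead")
    stop("regularized covariance could not be factorized")
  }
  if (tag == "cca") {
    ## guard against near-singularity that Cholesky tolerates numerically
    if (rcond(Cxx) < 1e-12 || rcond(Cyy) < 1e-12)
      stop("singular covariance matrix (p or q too large for n); ",
           "use fitRCCA() with positive regularization instead")
  }
  ## K = Rx^-T Cxy Ry^-1; canonical values = singular values of K
  K <- backsolveT(Rx, t(backsolveT(Ry, t(Cxy))))
  sv <- svd(K, nu = ndim, nv = ndim)
  A <- backsolve(Rx, sv$u)
  B <- backsolve(Ry, sv$v)
  ## deterministic sign: largest-|entry| of each X loading positive
  for (l in seq_len(ndim)) {
    top <- which.max(abs(A[, l]))
    if (A[top, l] < 0) { A[, l] <- -A[, l]; B[, l] <- -B[, l] }
  }
  dimnames(A) <- list(colnames(X), NULL)
  dimnames(B) <- list(colnames(Y), NULL)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  U <- Xc %*% A; V <- Yc %*% B
  rownames(U) <- rownames(V) <- rownames(X)
  new("ProjectionFit",
      method = tag, ndim = ndim,
      xLoadings = A, yLoadings = B, xVariates = U, yVariates = V,
      rho = sv$d[seq_len(ndim)],
      coefX = matrix(NA_real_, p, ndim, dimnames = list(colnames(X), NULL)),
      coefY = matrix(NA_real_, q, ndim, dimnames = list(colnames(Y), NULL)),
      sdU = apply(U, 2, stats::sd), sdV = apply(V, 2, stats::sd),
      lambda = c(lambda1, lambda2),
      keepX = rep(p, ndim), keepY = rep(q, ndim),
      residNorms = rep(NA_real_, ndim))
}

## solve t(R) %*% Z = M for upper-triangular R
backsolveT <- function(R, M) backsolve(R, M, transpose = TRUE)

#' Tune the rCCA ridge parameters by cross-validation
#'
#' Evaluates every (lambda1, lambda2) pair on a grid by k-fold
#' cross-validation: for each fold the first canonical pair is fitted on the
#' training samples, the held-out samples are projected, and the correlation
#' of the held-out variates is recorded. The pair maximizing the mean
#' held-out correlation is returned; fold assignment is deterministic given
#' the seed, and ties go to the earliest grid pair.
#'
#' @param data a standardized [PairedOmics-class].
#' @param grid numeric vector of candidate lambda values (the grid of pairs
#'   is its Cartesian square); default 11 log-spaced points in [1e-3, 1].
#' @param nFolds number of folds (>= 2).
#' @param seed seed for the fold assignment.
#' @return list with `lambda1`, `lambda2` and the full `scores` table.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' tuneRCCA(pd, grid = c(0.1, 1), nFolds = 3, seed = 1)$lambda1
#' @export
tuneRCCA <- function(data, grid = 10^seq(-3, 0, length.out = 11),
                     nFolds = 5, seed = 42) {
  requireStandardized(data)
  if (!length(grid) || any(grid < 0))
    stop("grid must be a nonempty vector of nonnegative values")
  n <- nrow(data@X)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L || nFolds > n)
    stop("nFolds must lie in [2, n]")
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(nFolds), length.out = n))
  pairs <- expand.grid(lambda1 = grid, lambda2 = grid,
                       KEEP.OUT.ATTRS = FALSE)
  pairs$score <- vapply(seq_len(nrow(pairs)), function(i) {
    cvScoreRCCA(data, pairs$lambda1[i], pairs$lambda2[i], folds)
  }, numeric(1))
  best <- which.max(pairs$score)
  list(lambda1 = pairs$lambda1[best], lambda2 = pairs$lambda2[best],
       scores = pairs)
}

cvScoreRCCA <- function(data, lambda1, lambda2, folds) {
  X <- data@X; Y <- data@Y
  cors <- vapply(sort(unique(folds)), function(k) {
    tr <- folds != k
    if (sum(tr) < 3L || sum(!tr) < 3L)
      stop("degenerate folds: need at least 3 samples per split")
    Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
    fit <- ccaEngine(pairedOmics(Xtr, Ytr, standardize = TRUE),
                     ndim = 1L, lambda1, lambda2, tag = "rcca")
    ## project held-out samples with the training centering/scaling
    ctrX <- colMeans(Xtr); sclX <- apply(Xtr, 2, stats::sd)
    ctrY <- colMeans(Ytr); sclY <- apply(Ytr, 2, stats::sd)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, ctrX), 2, sclX, "/")
    Yte <- sweep(sweep(Y[!tr, , drop = FALSE], 2, ctrY), 2, sclY, "/")
    u <- Xte %*% fit@xLoadings[, 1]
    v <- Yte %*% fit@yLoadings[, 1]
    if (stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12) return(0)
    stats::cor(u, v)
  }, numeric(1))
  mean(cors)
}
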