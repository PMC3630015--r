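#' Partial least squares for two blocks
#'
#' Iterative (NIPALS-style) PLS maximizing the covariance between latent
#' variates U = Xa and V = Yb under unit-norm loading vectors. Two deflation
#' modes are supported. In regression mode the relationship is directional
#' (X predicts Y): both blocks are deflated on the X variate U. In canonical
#' mode the relationship is symmetric: X is deflated on U and Y on V.
#'
#' The per-dimension statistic `rho` is the sample correlation of the paired
#' latent variates. Loadings are sign-fixed so that the largest-magnitude
#' entry of each X loading is positive, making fits deterministic.
#'
#' @param data a standardized [PairedOmics-class].
#' @param ndim number of dimensions to extract.
#' @param mode `"regression"` or `"canonical"` (abbreviations allowed).
#' @param tol convergence tolerance on the loading update (default 1e-9).
#' @param maxit maximum NIPALS iterations per dimension (default 500).
#' @return a [ProjectionFit-class] with method `"pls-reg"` or `"pls-can"`.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' fit <- fitPLS(pd, ndim = 3, mode = "canonical")
#' latentCor(fit)
#' @seealso [fitSPLS()] for the sparse variant.
#' @export
fitPLS <- function(data, ndim, mode = c("regression", "canonical"),
                   tol = 1e-9, maxit = 500L) {
  mode <- match.arg(mode)
  plsEngine(data, ndim, mode, keepX = NULL, keepY = NULL,
            tol = tol, maxit = maxit)
}

#' Sparse partial least squares
#'
#' PLS with lasso-type selection expressed as exact per-dimension selection
#' counts: inside each NIPALS iteration the unnormalized loading is
#' soft-thresholded so that exactly `keepX[l]` (resp. `keepY[l]`) entries
#' stay nonzero, then renormalized. With full counts the fit reduces to
#' [fitPLS()].
#'
#' @inheritParams fitPLS
#' @param keepX,keepY number of variables to retain per dimension; scalars
#'   are recycled over dimensions.
#' @return a [ProjectionFit-class] with method `"spls-reg"` or `"spls-can"`.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' sf <- fitSPLS(pd, ndim = 2, mode = "canonical", keepX = 23, keepY = 17)
#' colSums(xLoadings(sf) != 0)
#' @export
fitSPLS <- function(data, ndim, mode = c("regression", "canonical"),
                    keepX, keepY, tol = 1e-9, maxit = 500L) {
  mode <- match.arg(mode)
  p <- ncol(data@X); q <- ncol(data@Y)
  keepX <- normalizeKeep(keepX, ndim, p, "keepX")
  keepY <- normalizeKeep(keepY, ndim, q, "keepY")
  plsEngine(data, ndim, mode, keepX = keepX, keepY = keepY,
            tol = tol, maxit = maxit)
}

normalizeKeep <- function(keep, ndim, nmax, what) {
  keep <- as.integer(keep)
  if (length(keep) == 1L) keep <- rep(keep, ndim)
  if (length(keep) != ndim)
    stop(sprintf("%s must have length 1 or ndim", what))
  if (any(keep < 1L) || any(keep > nmax))
    stop(sprintf("%s must lie in [1, %d]", what, nmax))
  keep
}

## Soft-threshold `w` so that exactly `keep` entries stay nonzero.
## Threshold level: midpoint between the keep-th and (keep+1)-th largest
## absolute values; ties are broken by variable index order, and tied
## selected entries are kept at half the gap to the next distinct value (or
## a small fraction of their magnitude when no gap exists) so the count
## contract holds exactly.
softSelect <- function(w, keep) {
  p <- length(w)
  if (keep >= p) return(w)
  aw <- abs(w)
  ord <- order(aw, seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  sel <- ord[seq_len(keep)]
  lam <- max(aw[ord[(keep + 1L):p]])
  out <- numeric(p)
  shrunk <- aw[sel] - lam
  zero <- shrunk <= 0
  if (any(zero)) shrunk[zero] <- pmax(aw[sel][zero] * 1e-8,
                                      .Machine$double.eps)
  out[sel] <- sign(w[sel]) * shrunk
  out
}

plsEngine <- function(data, ndim, mode, keepX, keepY, tol, maxit) {
  requireStandardized(data)
  X <- data@X; Y <- data@Y
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ndim <- as.integer(ndim)
  sparse <- !is.null(keepX)
  maxd <- if (mode == "regression") p else min(p, q)
  if (ndim < 1L || ndim > maxd)
    stop(sprintf("ndim must lie in [1, %d] for this mode", maxd))
  E <- X; F <- Y
  A <- matrix(0, p, ndim, dimnames = list(colnames(X), NULL))
  B <- matrix(0, q, ndim, dimnames = list(colnames(Y), NULL))
  U <- matrix(0, n, ndim, dimnames = list(rownames(X), NULL))
  V <- matrix(0, n, ndim, dimnames = list(rownames(X), NULL))
  Phi <- matrix(0, p, ndim, dimnames = list(colnames(X), NULL))
  Psi <- matrix(0, q, ndim, dimnames = list(colnames(Y), NULL))
  rho <- sdU <- sdV <- resid <- numeric(ndim)
  for (l in seq_len(ndim)) {
    if (sum(E^2) < 1e-12 || sum(F^2) < 1e-12)
      stop(sprintf("rank exhausted before dimension %d", l))
    ## start from the leading singular pair of the residual cross-product:
    ## the fixed point NIPALS converges to for the dense fit, and a stable
    ## basin for the soft-thresholded one
    v <- F %*% svd(crossprod(E, F), nu = 0L, nv = 1L)$v[, 1]
    a.old <- rep(Inf, p)
    conv <- FALSE
    for (it in seq_len(maxit)) {
      a <- crossprod(E, v)
      if (sparse) a <- softSelect(a, keepX[l])
      na <- sqrt(sum(a^2))
      if (na < 1e-300) stop(sprintf("degenerate loading at dimension %d", l))
      a <- a / na
      u <- E %*% a
      b <- crossprod(F, u)
      if (sparse) b <- softSelect(b, keepY[l])
      b <- b / sqrt(sum(b^2))
      v <- F %*% b
      if (max(abs(a - a.old)) < tol) { conv <- TRUE; break }
      a.old <- a
    }
    if (!conv)
      stop(sprintf("NIPALS did not converge at dimension %d (%d iterations)",
                   l, maxit))
    ## deterministic sign: largest-|entry| of the X loading positive
    top <- which.max(abs(a))
    if (a[top] < 0) { a <- -a; u <- -u; b <- -b; v <- -v }
    rho[l] <- stats::cor(u, v)
    sdU[l] <- stats::sd(u)
    sdV[l] <- stats::sd(v)
    phi <- crossprod(E, u) / sum(u^2)
    E <- E - u %*% t(phi)
    if (mode == "regression") {
      psi <- crossprod(F, u) / sum(u^2)
      F <- F - u %*% t(psi)
    } else {
      psi <- crossprod(F, v) / sum(v^2)
      F <- F - v %*% t(psi)
    }
    A[, l] <- a; B[, l] <- b; U[, l] <- u; V[, l] <- v
    Phi[, l] <- phi; Psi[, l] <- psi
    resid[l] <- sqrt(sum(F^2))
  }
  tag <- paste0(if (sparse) "spls" else "pls",
                if (mode == "regression") "-reg" else "-can")
  new("ProjectionFit",
      method = tag, ndim = ndim,
      xLoadings = A, yLoadings = B, xVariates = U, yVariates = V,
      rho = rho, coefX = Phi, coefY = Psi, sdU = sdU, sdV = sdV,
      lambda = c(NA_real_, NA_real_),
      keepX = if (sparse) keepX else rep(p, ndim),
      keepY = if (sparse) keepY else rep(q, ndim),
      residNorms = resid)
}

#' Variables selected by a sparse fit
#'
#' Union of the variables with a nonzero loading on any of the first `d`
#' dimensions (all variables for non-sparse fits).
#'
#' @param fit a [ProjectionFit-class].
#' @param d number of leading dimensions to consider (default all).
#' @return list with character vectors `x` and `y`.
#' @export
selectedVariables <- function(fit, d = nDim(fit)) {
  d <- checkDims(fit, d)
  idx <- seq_len(d)
  list(x = rownames(fit@xLoadings)[rowSums(fit@xLoadings[, idx,
                                                         drop = FALSE] != 0) > 0],
       y = rownames(fit@yLoadings)[rowSums(fit@yLoadings[, idx,
                                                         drop = FALSE] != 0) > 0])
}

checkDims <- function(fit, d) {
  d <- as.integer(d)
  if (d < 1L || d > fit@ndim)
    stop(sprintf("d must lie in [1, %d]", fit@ndim))
  d
}
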