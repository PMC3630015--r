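#' Construct a simulation design
#'
#' The default design draws two data sets of 30 samples: X holds three
#' independent groups of 10, 10 and 3 cross-correlated variables (padded with
#' independent noise to 100 columns) and Y the matched groups of 10, 5 and 2
#' variables (padded to 50). Group A is negatively cross-correlated with
#' magnitudes spanning 0.51--0.93, group B positively with 0.50--0.85, and
#' group C with magnitudes 0.81--0.93, positive towards the first C-group Y
#' variable and negative towards the second.
#'
#' @param nSamples number of samples.
#' @param xBlocks,yBlocks named integer vectors of group sizes (same names).
#' @param crossRanges named list of `c(lo, hi)` cross-correlation magnitude
#'   ranges, one per group.
#' @param crossSigns named list of +1/-1 vectors, one sign per Y variable of
#'   the group.
#' @param withinShare extra within-block shared-variance fraction in [0, 1);
#'   0 leaves within-block correlations fully determined by the cross ranges.
#' @param nNoiseX,nNoiseY number of independent N(0,1) noise variables
#'   appended to X and Y.
#' @param seed default seed used by [simulatePair()].
#' @return a [SimulationDesign-class] object.
#' @examples
#' d <- simulationDesign()
#' d
#' @export
simulationDesign <- function(nSamples = 30,
                             xBlocks = c(A = 10L, B = 10L, C = 3L),
                             yBlocks = c(A = 10L, B = 5L, C = 2L),
                             crossRanges = list(A = c(0.51, 0.93),
                                                B = c(0.50, 0.85),
                                                C = c(0.81, 0.93)),
                             crossSigns = list(A = rep(-1, 10),
                                               B = rep(1, 5),
                                               C = c(1, -1)),
                             withinShare = 0,
                             nNoiseX = 77,
                             nNoiseY = 33,
                             seed = 42) {
  new("SimulationDesign",
      nSamples = as.integer(nSamples),
      xBlocks = vapply(xBlocks, as.integer, integer(1)),
      yBlocks = vapply(yBlocks, as.integer, integer(1)),
      crossRanges = crossRanges,
      crossSigns = crossSigns,
      withinShare = withinShare,
      nNoiseX = as.integer(nNoiseX),
      nNoiseY = as.integer(nNoiseY),
      seed = as.integer(seed))
}

## Factor loadings whose pairwise products span [lo, hi] exactly:
## squared loadings evenly spaced between sqrt(lo*lo')... we place the
## squared loadings on an even grid from lo*s to hi/s with s = sqrt(hi/lo)
## folded so that the extreme products are attained at the endpoints.
## Simpler and exact: loadings sqrt(evenly spaced squared values) on both
## sides with common endpoints sqrt(lo), sqrt(hi): products then span
## [lo, hi] with both endpoints attained.
blockLoadings <- function(range, n) {
  if (n == 1L) return(sqrt(range[2]))
  sqrt(seq(range[1], range[2], length.out = n))
}

designIds <- function(design) {
  xid <- unlist(lapply(names(design@xBlocks), function(g)
    paste0("X", g, seq_len(design@xBlocks[[g]]))), use.names = FALSE)
  yid <- unlist(lapply(names(design@yBlocks), function(g)
    paste0("Y", g, seq_len(design@yBlocks[[g]]))), use.names = FALSE)
  list(x = c(xid, paste0("NX", seq_len(design@nNoiseX))),
       y = c(yid, paste0("NY", seq_len(design@nNoiseY))))
}

#' Is a variable id a noise id?
#'
#' Noise variables produced by the generator carry the reserved prefixes
#' `NX` / `NY`, so downstream network tests can count them.
#'
#' @param ids character vector of variable ids.
#' @return logical vector.
#' @export
isNoiseId <- function(ids) grepl("^N[XY][0-9]+$", ids)

#' Build the population covariance matrix of a design
#'
#' Assembles the (p+q) x (p+q) covariance over the concatenated (X, Y)
#' variables. Each matched block pair shares one latent factor; X loadings
#' are positive and Y loadings carry the per-variable signs of the design, so
#' the cross-block correlations are products of loadings whose squared values
#' are evenly spaced over the requested range (endpoints attained exactly).
#' Unmatched groups and all noise variables are uncorrelated. The matrix has
#' unit diagonal and is positive definite by construction, so no
#' eigenvalue repair is ever needed.
#'
#' @param design a [SimulationDesign-class].
#' @return covariance matrix with variable ids as dimnames.
#' @examples
#' S <- buildCovariance(simulationDesign())
#' range(S[paste0("XA", 1:10), paste0("YA", 1:10)])
#' @export
buildCovariance <- function(design) {
  validObject(design)
  groups <- names(design@xBlocks)
  p <- sum(design@xBlocks) + design@nNoiseX
  q <- sum(design@yBlocks) + design@nNoiseY
  ## factor loading matrix: one shared factor per group, plus (optionally)
  ## one within-block factor per group and side
  nf <- length(groups) * 3L
  LX <- matrix(0, p, nf)
  LY <- matrix(0, q, nf)
  xoff <- 0L; yoff <- 0L
  for (i in seq_along(groups)) {
    g <- groups[i]
    nx <- design@xBlocks[[g]]; ny <- design@yBlocks[[g]]
    lx <- blockLoadings(design@crossRanges[[g]], nx)
    ly <- blockLoadings(design@crossRanges[[g]], ny) * design@crossSigns[[g]]
    LX[xoff + seq_len(nx), i] <- lx
    LY[yoff + seq_len(ny), i] <- ly
    if (design@withinShare > 0) {
      LX[xoff + seq_len(nx), length(groups) + i] <-
        design@withinShare * sqrt(1 - lx^2)
      LY[yoff + seq_len(ny), 2L * length(groups) + i] <-
        design@withinShare * sqrt(1 - ly^2)
    }
    xoff <- xoff + nx; yoff <- yoff + ny
  }
  L <- rbind(LX, LY)
  Sigma <- tcrossprod(L)
  diag(Sigma) <- 1
  ids <- designIds(design)
  dimnames(Sigma) <- list(c(ids$x, ids$y), c(ids$x, ids$y))
  ## construction is PD; verify the targeted entries really sit in range
  for (i in seq_along(groups)) {
    g <- groups[i]
    xi <- which(LX[, i] != 0); yi <- which(LY[, i] != 0)
    if (length(xi) && length(yi)) {
      cross <- abs(Sigma[xi, p + yi, drop = FALSE])
      r <- design@crossRanges[[g]]
      if (min(cross) < r[1] - 1e-10 || max(cross) > r[2] + 1e-10)
        stop(sprintf(
          "cross-correlations of block %s left the requested range", g))
    }
  }
  Sigma
}

#' Simulate a paired data set from a design
#'
#' Draws `nSamples` rows from the multivariate normal with the covariance of
#' [buildCovariance()], splits the columns into the X and Y blocks, attaches
#' ids encoding block membership (noise ids prefixed `NX`/`NY`) and
#' standardizes every column. Identical (design, seed) pairs give
#' bit-identical output.
#'
#' @param design a [SimulationDesign-class].
#' @param seed integer seed; defaults to the design's seed.
#' @param standardize standardize columns (default TRUE).
#' @return a [PairedOmics-class] data set.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' dim(pd)
#' @export
simulatePair <- function(design, seed = design@seed, standardize = TRUE) {
  Sigma <- buildCovariance(design)
  p <- sum(design@xBlocks) + design@nNoiseX
  q <- sum(design@yBlocks) + design@nNoiseY
  n <- design@nSamples
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("covariance matrix is not positive semi-definite")
  set.seed(as.integer(seed))
  Z <- MASS::mvrnorm(n, mu = rep(0, p + q), Sigma = Sigma)
  rownames(Z) <- paste0("S", seq_len(n))
  X <- Z[, seq_len(p), drop = FALSE]
  Y <- Z[, p + seq_len(q), drop = FALSE]
  pairedOmics(X, Y, standardize = standardize)
}
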