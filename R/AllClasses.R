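#' @import methods
NULL

## ---------------------------------------------------------------------------
## SimulationDesign
## ---------------------------------------------------------------------------

#' Block-structured simulation design for paired data
#'
#' Describes a paired-data simulation in which groups of X variables are
#' cross-correlated with matched groups of Y variables through shared latent
#' factors, and the remaining variables are independent standard-normal noise.
#' Each associated block pair is driven by one latent factor; the squared
#' factor loadings are evenly spaced so that the population cross-correlations
#' span exactly the requested range (endpoints attained). The resulting
#' covariance matrix is positive definite by construction and has unit
#' diagonal.
#'
#' @slot nSamples number of samples drawn per data set.
#' @slot xBlocks named integer vector, sizes of the correlated X groups.
#' @slot yBlocks named integer vector (same names), sizes of the matched Y
#'   groups.
#' @slot crossRanges named list of length-2 numerics `c(lo, hi)`,
#'   `0 < lo <= hi <= 1`: the magnitude range spanned by the cross-block
#'   correlations of each group.
#' @slot crossSigns named list of sign vectors (+1/-1), one entry per Y
#'   variable of the group, giving the sign of its correlations with the
#'   group's X variables.
#' @slot withinShare fraction in [0, 1) of each variable's residual standard
#'   deviation assigned to an extra block-level shared factor, raising
#'   within-block correlations without touching cross-block entries.
#' @slot nNoiseX,nNoiseY number of independent noise variables appended to
#'   each data set.
#' @slot seed default seed used by [simulatePair()] when none is given.
#' @seealso [simulationDesign()], [buildCovariance()], [simulatePair()]
#' @export
setClass("SimulationDesign",
  representation(
    nSamples    = "integer",
    xBlocks     = "integer",
    yBlocks     = "integer",
    crossRanges = "list",
    crossSigns  = "list",
    withinShare = "numeric",
    nNoiseX     = "integer",
    nNoiseY     = "integer",
    seed        = "integer"
  )
)

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (length(object@xBlocks) != length(object@yBlocks))
    msg <- c(msg, "xBlocks and yBlocks must have the same length")
  if (!identical(names(object@xBlocks), names(object@yBlocks)))
    msg <- c(msg, "xBlocks and yBlocks must share block names")
  if (any(object@xBlocks < 1L) || any(object@yBlocks < 1L))
    msg <- c(msg, "all block sizes must be positive")
  if (object@nNoiseX < 0L || object@nNoiseY < 0L)
    msg <- c(msg, "noise counts must be nonnegative")
  if (length(object@withinShare) != 1L ||
      object@withinShare < 0 || object@withinShare >= 1)
    msg <- c(msg, "withinShare must be a single value in [0, 1)")
  nms <- names(object@xBlocks)
  if (!identical(names(object@crossRanges), nms) ||
      !identical(names(object@crossSigns), nms))
    msg <- c(msg, "crossRanges and crossSigns must be named like the blocks")
  for (g in nms) {
    r <- object@crossRanges[[g]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < 0 || r[2] > 1)
      msg <- c(msg, sprintf(
        "crossRanges[['%s']] must be c(lo, hi) with 0 <= lo <= hi <= 1", g))
    s <- object@crossSigns[[g]]
    if (length(s) != object@yBlocks[[g]] || !all(abs(s) == 1))
      msg <- c(msg, sprintf(
        "crossSigns[['%s']] must hold one +1/-1 per Y variable of the block",
        g))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PairedOmics
## ---------------------------------------------------------------------------

#' Two data matrices sharing samples
#'
#' Container for the two blocks X (n x p) and Y (n x q) measured on the same
#' n samples. Rows are aligned by sample id; when `standardized` is TRUE each
#' column has zero mean and unit variance.
#'
#' @slot X,Y numeric matrices with matching rownames (sample ids) and unique
#'   colnames (variable ids).
#' @slot standardized logical flag.
#' @seealso [pairedOmics()], [readPaired()]
#' @export
setClass("PairedOmics",
  representation(X = "matrix", Y = "matrix", standardized = "logical")
)

setValidity("PairedOmics", function(object) {
  msg <- character()
  X <- object@X; Y <- object@Y
  if (!is.numeric(X) || !is.numeric(Y))
    msg <- c(msg, "X and Y must be numeric matrices")
  if (nrow(X) != nrow(Y))
    msg <- c(msg, "X and Y must have the same number of rows")
  if (is.null(rownames(X)) || is.null(rownames(Y)) ||
      !identical(rownames(X), rownames(Y)))
    msg <- c(msg, "X and Y must carry identical sample rownames")
  if (anyDuplicated(colnames(X)) || anyDuplicated(colnames(Y)))
    msg <- c(msg, "variable ids must be unique within each block")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    msg <- c(msg, "all entries must be finite")
  if (isTRUE(object@standardized)) {
    chk <- function(M, tag) {
      mu <- colMeans(M)
      v  <- apply(M, 2, stats::var)
      if (max(abs(mu)) > 1e-8 || max(abs(v - 1)) > 1e-8)
        sprintf("%s is flagged standardized but has off-unit columns", tag)
    }
    msg <- c(msg, chk(X, "X"), chk(Y, "Y"))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ProjectionFit
## ---------------------------------------------------------------------------

#' Result of a two-block projection fit
#'
#' Holds the loadings, variates and per-dimension statistics of any of the six
#' supported fits: `cca`, `rcca`, `pls-reg`, `pls-can`, `spls-reg`,
#' `spls-can`.
#'
#' For the PLS family, loading vectors are unit-norm and `rho` is the
#' correlation between paired latent variates. For the CCA family, variates
#' have unit variance in the (regularized) metric and `rho` holds the
#' canonical values reported by the method: the singular values of the
#' whitened cross-covariance, which for an unregularized fit equal the
#' empirical correlations of the canonical variate pairs.
#'
#' @slot method character, one of the six method tags.
#' @slot ndim number of fitted dimensions d.
#' @slot xLoadings,yLoadings p x d and q x d loading matrices (a^l, b^l).
#' @slot xVariates,yVariates n x d variate matrices (U, V).
#' @slot rho per-dimension association statistic (length d).
#' @slot coefX,coefY regression coefficients of the X (resp. Y) variables on
#'   the variates used for deflation (phi^l, psi^l; PLS family).
#' @slot sdU,sdV standard deviations of the U and V variates (length d).
#' @slot lambda ridge parameters c(lambda1, lambda2) (CCA family; NA
#'   otherwise).
#' @slot keepX,keepY per-dimension selection counts (sparse family; full
#'   counts otherwise).
#' @slot residNorms Frobenius norm of the deflated Y block after each
#'   dimension.
#' @seealso [fitPLS()], [fitSPLS()], [fitCCA()], [fitRCCA()]
#' @export
setClass("ProjectionFit",
  representation(
    method     = "character",
    ndim       = "integer",
    xLoadings  = "matrix",
    yLoadings  = "matrix",
    xVariates  = "matrix",
    yVariates  = "matrix",
    rho        = "numeric",
    coefX      = "matrix",
    coefY      = "matrix",
    sdU        = "numeric",
    sdV        = "numeric",
    lambda     = "numeric",
    keepX      = "integer",
    keepY      = "integer",
    residNorms = "numeric"
  )
)

setValidity("ProjectionFit", function(object) {
  msg <- character()
  d <- object@ndim
  ok <- c(
    length(object@method) == 1L,
    object@method %in% c("cca", "rcca", "pls-reg", "pls-can",
                         "spls-reg", "spls-can"),
    ncol(object@xLoadings) == d, ncol(object@yLoadings) == d,
    ncol(object@xVariates) == d, ncol(object@yVariates) == d,
    length(object@rho) == d, length(object@sdU) == d,
    length(object@sdV) == d,
    nrow(object@xVariates) == nrow(object@yVariates)
  )
  if (!all(ok)) msg <- c(msg, "inconsistent dimensions across slots")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## VariableCoordinates
## ---------------------------------------------------------------------------

#' Correlations of the variables with the reference variates
#'
#' One row per variable, one column per retained dimension; entry (j, l) is
#' the sample correlation between variable j and the l-th reference variate
#' (the equiangular vector Z = U + V for the CCA family, the U -- and, in
#' canonical mode, V -- variates for the PLS family). For sparse fits only
#' the selected variables are represented.
#'
#' @slot x p x d coordinate matrix of the X variables.
#' @slot y q x d coordinate matrix of the Y variables.
#' @slot reference one of "equiangular", "X-variate", "XY-variates".
#' @slot d number of retained dimensions.
#' @seealso [variableCoords()], [similarityMatrix()], [circleCoords()]
#' @export
setClass("VariableCoordinates",
  representation(x = "matrix", y = "matrix", reference = "character",
                 d = "integer")
)

setValidity("VariableCoordinates", function(object) {
  msg <- character()
  if (ncol(object@x) != object@d || ncol(object@y) != object@d)
    msg <- c(msg, "coordinate matrices must have d columns")
  if (max(abs(object@x), abs(object@y), 0) > 1 + 1e-8)
    msg <- c(msg, "coordinates are correlations and must lie in [-1, 1]")
  if (!object@reference %in% c("equiangular", "X-variate", "XY-variates"))
    msg <- c(msg, "unknown reference kind")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimilarityMatrix
## ---------------------------------------------------------------------------

#' Pair-wise similarity matrix between the X and Y variables
#'
#' The p x q matrix M = x y' of inner products of variable coordinates on the
#' retained dimensions; rows are X variables, columns Y variables. Entries
#' approximate the Pearson cross-correlations.
#'
#' @slot M numeric matrix (rows = X variables, columns = Y variables).
#' @slot d number of dimensions used.
#' @slot method method tag of the originating fit.
#' @seealso [similarityMatrix()], [relevanceNetwork()], [clusterSimilarity()]
#' @export
setClass("SimilarityMatrix",
  representation(M = "matrix", d = "integer", method = "character")
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  if (any(!is.finite(object@M)))
    msg <- c(msg, "M must be finite")
  if (length(object@M) && max(abs(object@M)) > 1 + 1e-8)
    msg <- c(msg, "entries of M must lie in [-1, 1]")
  if (is.null(rownames(object@M)) || is.null(colnames(object@M)))
    msg <- c(msg, "M must carry variable ids as dimnames")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RelevanceNetwork
## ---------------------------------------------------------------------------

#' Thresholded bipartite association network
#'
#' Bipartite graph over X and Y variables whose edges are the similarity
#' entries with |M_jk| >= threshold; nodes without any edge are dropped.
#'
#' @slot nodes data.frame with columns `id`, `side` ("X" or "Y").
#' @slot edges data.frame with columns `x`, `y`, `weight`, `sign`.
#' @slot threshold the absolute-value threshold used.
#' @seealso [relevanceNetwork()], [networkComponents()], [exportNetwork()]
#' @export
setClass("RelevanceNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 threshold = "numeric")
)

setValidity("RelevanceNetwork", function(object) {
  msg <- character()
  ed <- object@edges; nd <- object@nodes
  if (!all(c("id", "side") %in% names(nd)))
    msg <- c(msg, "nodes needs columns id, side")
  if (!all(c("x", "y", "weight", "sign") %in% names(ed)))
    msg <- c(msg, "edges needs columns x, y, weight, sign")
  if (length(msg)) return(msg)
  xs <- nd$id[nd$side == "X"]; ys <- nd$id[nd$side == "Y"]
  if (nrow(ed)) {
    if (!all(ed$x %in% xs) || !all(ed$y %in% ys))
      msg <- c(msg, "every edge must join an X node to a Y node")
    if (any(abs(ed$weight) < object@threshold))
      msg <- c(msg, "every edge weight must satisfy |weight| >= threshold")
  }
  touched <- unique(c(ed$x, ed$y))
  if (!setequal(nd$id, touched))
    msg <- c(msg, "isolated nodes must not be present")
  if (object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CIMResult
## ---------------------------------------------------------------------------

#' Dual hierarchical clustering of a similarity matrix
#'
#' Rows and columns of M clustered independently; the reordered matrix, the
#' two permutations and the two merge trees are retained for rendering and
#' inspection.
#'
#' @slot matrix the reordered similarity matrix.
#' @slot rowOrder,colOrder integer permutations of the original indices.
#' @slot rowDend,colDend `hclust` trees whose leaf order equals the stored
#'   permutations.
#' @slot distance,linkage names of the metric and agglomeration method used.
#' @seealso [clusterSimilarity()], [plotCIM()]
#' @export
setClass("CIMResult",
  representation(
    matrix   = "matrix",
    rowOrder = "integer",
    colOrder = "integer",
    rowDend  = "ANY",
    colDend  = "ANY",
    distance = "character",
    linkage  = "character"
  )
)

setValidity("CIMResult", function(object) {
  msg <- character()
  if (!identical(sort(object@rowOrder), seq_len(nrow(object@matrix))))
    msg <- c(msg, "rowOrder must be a permutation of the row indices")
  if (!identical(sort(object@colOrder), seq_len(ncol(object@matrix))))
    msg <- c(msg, "colOrder must be a permutation of the column indices")
  if (!inherits(object@rowDend, "hclust") ||
      !inherits(object@colDend, "hclust"))
    msg <- c(msg, "rowDend and colDend must be hclust objects")
  else {
    if (!identical(object@rowDend$order, object@rowOrder) ||
        !identical(object@colDend$order, object@colOrder))
      msg <- c(msg, "dendrogram leaf order must equal the stored permutation")
  }
  if (length(msg)) msg else TRUE
})
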