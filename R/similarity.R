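#' Variable coordinates on the reference variates
#'
#' Projects every variable onto the reference axes of the fit by computing
#' sample correlations. For the CCA family the references are the
#' equiangular vectors Z^l = U^l + V^l, treating X and Y symmetrically. For
#' the PLS family the X coordinates are correlations with the U variates in
#' both modes; the Y coordinates use U in regression mode and V in canonical
#' mode. For sparse fits, coordinates are computed only for the variables
#' selected on the first `d` dimensions.
#'
#' Coordinates are always computed as empirical correlations with the stored
#' variates; the closed forms through the deflation coefficients (e.g.
#' cor(X^j, U^l) = sd(U^l) * phi^l_j) hold for standardized data and serve
#' as independent checks.
#'
#' @param fit a [ProjectionFit-class].
#' @param data the [PairedOmics-class] the fit was computed from.
#' @param d number of leading dimensions to retain (default all fitted).
#' @return a [VariableCoordinates-class] object.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' fit <- fitPLS(pd, 3, "canonical")
#' co <- variableCoords(fit, pd)
#' range(xCoords(co))
#' @export
variableCoords <- function(fit, data, d = nDim(fit)) {
  requireStandardized(data)
  d <- checkDims(fit, d)
  idx <- seq_len(d)
  U <- fit@xVariates[, idx, drop = FALSE]
  V <- fit@yVariates[, idx, drop = FALSE]
  if (nrow(U) != nrow(data@X))
    stop("fit and data disagree on the number of samples")
  if (fit@method %in% c("cca", "rcca")) {
    Z <- U + V
    cx <- stats::cor(data@X, Z)
    cy <- stats::cor(data@Y, Z)
    ref <- "equiangular"
  } else {
    sel <- selectedVariables(fit, d)
    cx <- stats::cor(data@X[, sel$x, drop = FALSE], U)
    if (grepl("-reg$", fit@method)) {
      cy <- stats::cor(data@Y[, sel$y, drop = FALSE], U)
      ref <- "X-variate"
    } else {
      cy <- stats::cor(data@Y[, sel$y, drop = FALSE], V)
      ref <- "XY-variates"
    }
  }
  colnames(cx) <- colnames(cy) <- paste0("dim", idx)
  new("VariableCoordinates", x = cx, y = cy, reference = ref,
      d = d)
}

#' Assemble the pair-wise similarity matrix
#'
#' Inner products of the X and Y variable coordinates over the retained
#' dimensions: M = x y', a p x q matrix (rows = X variables) whose entries
#' approximate the Pearson cross-correlations between the two blocks. For
#' sparse fits the matrix covers only the selected variables.
#'
#' @param coords a [VariableCoordinates-class], typically from
#'   [variableCoords()].
#' @return a [SimilarityMatrix-class].
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' M <- similarityMatrix(variableCoords(fitPLS(pd, 3, "canonical"), pd))
#' dim(M)
#' @export
similarityMatrix <- function(coords) {
  if (!is(coords, "VariableCoordinates"))
    stop("`coords` must be a VariableCoordinates object")
  M <- tcrossprod(coords@x, coords@y)
  new("SimilarityMatrix", M = M, d = coords@d, method = "unknown")
}

#' One-call similarity matrix from a fit
#'
#' Convenience wrapper chaining [variableCoords()] and [similarityMatrix()],
#' carrying the fit's method tag along.
#'
#' @inheritParams variableCoords
#' @return a [SimilarityMatrix-class].
#' @export
pairwiseSimilarity <- function(fit, data, d = nDim(fit)) {
  co <- variableCoords(fit, data, d)
  M <- tcrossprod(co@x, co@y)
  new("SimilarityMatrix", M = M, d = co@d, method = fit@method)
}
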