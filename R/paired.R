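#' Assemble a paired data set
#'
#' Validates and (optionally) column-standardizes two matrices measured on
#' the same samples. If both matrices carry rownames the rows of `Y` are
#' aligned to the sample order of `X`; mismatched sample sets are an error
#' naming the offending ids. Zero-variance columns cannot be standardized and
#' are rejected by name.
#'
#' @param X,Y numeric matrices (samples x variables).
#' @param standardize center and scale every column (default TRUE).
#' @return a [PairedOmics-class] object.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10),
#'                                               paste0("g", 1:4)))
#' Y <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10),
#'                                               paste0("m", 1:3)))
#' pairedOmics(X, Y)
#' @export
pairedOmics <- function(X, Y, standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y))
    stop("X and Y must be numeric matrices")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  if (is.null(rownames(X)) && is.null(rownames(Y))) {
    if (nrow(X) != nrow(Y))
      stop("X and Y must have the same number of rows")
    rownames(X) <- rownames(Y) <- paste0("S", seq_len(nrow(X)))
  } else if (is.null(rownames(X)) || is.null(rownames(Y))) {
    stop("either both or neither matrix must carry sample rownames")
  } else {
    onlyX <- setdiff(rownames(X), rownames(Y))
    onlyY <- setdiff(rownames(Y), rownames(X))
    if (length(onlyX) || length(onlyY))
      stop("sample sets differ between X and Y; missing from Y: [",
           paste(onlyX, collapse = ", "), "]; missing from X: [",
           paste(onlyY, collapse = ", "), "]")
    if (anyDuplicated(rownames(X)) || anyDuplicated(rownames(Y)))
      stop("duplicated sample ids")
    Y <- Y[rownames(X), , drop = FALSE]
  }
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite entries in the data")
  if (standardize) {
    X <- standardizeColumns(X, "X")
    Y <- standardizeColumns(Y, "Y")
  }
  new("PairedOmics", X = X, Y = Y, standardized = isTRUE(standardize))
}

standardizeColumns <- function(M, tag) {
  v <- apply(M, 2, stats::var)
  bad <- colnames(M)[v < .Machine$double.eps]
  if (length(bad))
    stop(sprintf("zero-variance column(s) in %s: %s", tag,
                 paste(bad, collapse = ", ")))
  M <- scale(M, center = TRUE, scale = TRUE)
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  M
}

requireStandardized <- function(data) {
  if (!is(data, "PairedOmics"))
    stop("`data` must be a PairedOmics object")
  if (!data@standardized)
    stop("this method requires standardized data; ",
         "rebuild with pairedOmics(..., standardize = TRUE)")
  invisible(data)
}
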