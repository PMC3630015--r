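#' Read a paired data set from two delimited files
#'
#' Each file holds a header row of variable ids and a first column of sample
#' ids; the delimiter (tab or comma) is sniffed from the header unless
#' forced. Samples are matched by id between the two files, the Y rows are
#' reordered to the X order, and columns are standardized when requested.
#' Mismatched sample sets, duplicate ids, non-numeric cells and
#' zero-variance columns are errors naming the offender.
#'
#' @param pathX,pathY paths to the X and Y matrices.
#' @param standardize center and scale the columns (default TRUE).
#' @param sep field delimiter; NULL (default) sniffs `\t` vs `,`.
#' @return a [PairedOmics-class].
#' @export
readPaired <- function(pathX, pathY, standardize = TRUE, sep = NULL) {
  X <- readMatrix(pathX, sep)
  Y <- readMatrix(pathY, sep)
  pairedOmics(X, Y, standardize = standardize)
}

readMatrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t"
           else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  as.matrix(df)
}

#' Write a paired data set as two delimited files
#'
#' Tab-separated with variable ids in the header and sample ids in the first
#' column, the format read back by [readPaired()]. Values are written in
#' full precision so a write/read round trip reproduces them bit-exactly.
#'
#' @param data a [PairedOmics-class].
#' @param pathX,pathY output paths.
#' @return invisibly, the two paths.
#' @export
writePaired <- function(data, pathX, pathY) {
  writeMatrix(data@X, pathX)
  writeMatrix(data@Y, pathY)
  invisible(c(pathX, pathY))
}

writeMatrix <- function(m, path) {
  df <- data.frame(sample = rownames(m),
                   as.data.frame(format(m, digits = 17, trim = TRUE,
                                        scientific = TRUE),
                                 check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix as TSV
#'
#' X variable ids as row names (first column), Y variable ids as header.
#'
#' @param M a [SimilarityMatrix-class] or matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSimilarity <- function(M, path) {
  writeMatrix2(asSimMatrix(M), path)
}

writeMatrix2 <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [writeSimilarity()]
#'
#' @param path TSV path.
#' @return a [SimilarityMatrix-class] with method tag `"file"`.
#' @export
readSimilarity <- function(path) {
  m <- readMatrix(path)
  new("SimilarityMatrix", M = m, d = NA_integer_, method = "file")
}

#' Serialize a projection fit to JSON
#'
#' Full-precision JSON holding every slot of the fit, so downstream stages
#' (similarity, plots) can run in a separate invocation.
#'
#' @param fit a [ProjectionFit-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFit <- function(fit, path) {
  obj <- list(
    method = fit@method, ndim = fit@ndim,
    xIds = rownames(fit@xLoadings), yIds = rownames(fit@yLoadings),
    sampleIds = rownames(fit@xVariates),
    xLoadings = fit@xLoadings, yLoadings = fit@yLoadings,
    xVariates = fit@xVariates, yVariates = fit@yVariates,
    rho = fit@rho, coefX = fit@coefX, coefY = fit@coefY,
    sdU = fit@sdU, sdV = fit@sdV, lambda = fit@lambda,
    keepX = fit@keepX, keepY = fit@keepY, residNorms = fit@residNorms)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Read a projection fit written by [writeFit()]
#'
#' @param path JSON path.
#' @return a [ProjectionFit-class].
#' @export
readFit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(m, rn) {
    m <- as.matrix(m)
    if (nrow(m) == length(rn)) rownames(m) <- rn
    m
  }
  num <- function(x) { x <- as.numeric(x); x[is.na(x)] <- NA_real_; x }
  new("ProjectionFit",
      method = o$method, ndim = as.integer(o$ndim),
      xLoadings = mat(o$xLoadings, o$xIds),
      yLoadings = mat(o$yLoadings, o$yIds),
      xVariates = mat(o$xVariates, o$sampleIds),
      yVariates = mat(o$yVariates, o$sampleIds),
      rho = num(o$rho), coefX = mat(o$coefX, o$xIds),
      coefY = mat(o$coefY, o$yIds),
      sdU = num(o$sdU), sdV = num(o$sdV), lambda = num(o$lambda),
      keepX = as.integer(o$keepX), keepY = as.integer(o$keepY),
      residNorms = num(o$residNorms))
}
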