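## Accessor and show methods for the S4 containers.

#' @rdname accessors
#' @export
setMethod("fitMethod", "ProjectionFit", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("nDim", "ProjectionFit", function(object) object@ndim)

#' @rdname accessors
#' @export
setMethod("xLoadings", "ProjectionFit", function(object) object@xLoadings)

#' @rdname accessors
#' @export
setMethod("yLoadings", "ProjectionFit", function(object) object@yLoadings)

#' @rdname accessors
#' @export
setMethod("xVariates", "ProjectionFit", function(object) object@xVariates)

#' @rdname accessors
#' @export
setMethod("yVariates", "ProjectionFit", function(object) object@yVariates)

#' @rdname accessors
#' @export
setMethod("latentCor", "ProjectionFit", function(object) object@rho)

#' @rdname accessors
#' @export
setMethod("xMatrix", "PairedOmics", function(object) object@X)

#' @rdname accessors
#' @export
setMethod("yMatrix", "PairedOmics", function(object) object@Y)

#' @rdname accessors
#' @export
setMethod("xCoords", "VariableCoordinates", function(object) object@x)

#' @rdname accessors
#' @export
setMethod("yCoords", "VariableCoordinates", function(object) object@y)

#' @rdname accessors
#' @export
setMethod("simMatrix", "SimilarityMatrix", function(object) object@M)

#' @rdname accessors
#' @export
setMethod("nDim", "SimilarityMatrix", function(object) object@d)

#' @rdname accessors
#' @export
setMethod("nDim", "VariableCoordinates", function(object) object@d)

#' @rdname accessors
#' @export
setMethod("netNodes", "RelevanceNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("netEdges", "RelevanceNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("netThreshold", "RelevanceNetwork", function(object) object@threshold)

#' @export
setMethod("dim", "PairedOmics", function(x)
  c(n = nrow(x@X), p = ncol(x@X), q = ncol(x@Y)))

#' @export
setMethod("dim", "SimilarityMatrix", function(x) dim(x@M))

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nSamples, "samples\n")
  cat("  X blocks:", paste(sprintf("%s=%d", names(object@xBlocks),
                                   object@xBlocks), collapse = ", "),
      sprintf("+ %d noise\n", object@nNoiseX))
  cat("  Y blocks:", paste(sprintf("%s=%d", names(object@yBlocks),
                                   object@yBlocks), collapse = ", "),
      sprintf("+ %d noise\n", object@nNoiseY))
  for (g in names(object@crossRanges)) {
    r <- object@crossRanges[[g]]
    cat(sprintf("  block %s: |cross-cor| in [%.2f, %.2f], Y signs %s\n",
                g, r[1], r[2],
                paste(ifelse(object@crossSigns[[g]] > 0, "+", "-"),
                      collapse = "")))
  }
  cat("  withinShare:", object@withinShare, " default seed:", object@seed,
      "\n")
})

setMethod("show", "PairedOmics", function(object) {
  d <- dim(object)
  cat(sprintf("PairedOmics: %d samples; X %d x %d, Y %d x %d (%s)\n",
              d["n"], d["n"], d["p"], d["n"], d["q"],
              if (object@standardized) "standardized" else "raw"))
})

setMethod("show", "ProjectionFit", function(object) {
  cat(sprintf("ProjectionFit <%s>: %d dimension(s), %d x-vars, %d y-vars\n",
              object@method, object@ndim, nrow(object@xLoadings),
              nrow(object@yLoadings)))
  cat("  rho:", paste(sprintf("%.4f", object@rho), collapse = " "), "\n")
  if (grepl("^spls", object@method)) {
    cat("  keepX:", paste(object@keepX, collapse = " "),
        " keepY:", paste(object@keepY, collapse = " "), "\n")
  }
  if (grepl("cca", object@method) && all(is.finite(object@lambda)))
    cat("  lambda:", paste(object@lambda, collapse = " "), "\n")
})

setMethod("show", "VariableCoordinates", function(object) {
  cat(sprintf(
    "VariableCoordinates (%s): %d X and %d Y variables on %d dimension(s)\n",
    object@reference, nrow(object@x), nrow(object@y), object@d))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix <%s, d=%d>: %d x %d, |M| in [%.3f, %.3f]\n",
              object@method, object@d, nrow(object@M), ncol(object@M),
              min(abs(object@M)), max(abs(object@M))))
})

setMethod("show", "RelevanceNetwork", function(object) {
  cat(sprintf(
    "RelevanceNetwork: %d nodes (%d X, %d Y), %d edges at threshold %.3f\n",
    nrow(object@nodes), sum(object@nodes$side == "X"),
    sum(object@nodes$side == "Y"), nrow(object@edges), object@threshold))
})

setMethod("show", "CIMResult", function(object) {
  cat(sprintf(
    "CIMResult: %d x %d matrix clustered (distance=%s, linkage=%s)\n",
    nrow(object@matrix), ncol(object@matrix), object@distance,
    object@linkage))
})
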