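#' Accessor generics
#'
#' Small accessor family for the S4 containers; use these rather than
#' reaching into slots.
#'
#' @param object an object of the matching class.
#' @param ... passed on to methods.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fitMethod", function(object) standardGeneric("fitMethod"))

#' @rdname accessors
#' @export
setGeneric("nDim", function(object) standardGeneric("nDim"))

#' @rdname accessors
#' @export
setGeneric("xLoadings", function(object) standardGeneric("xLoadings"))

#' @rdname accessors
#' @export
setGeneric("yLoadings", function(object) standardGeneric("yLoadings"))

#' @rdname accessors
#' @export
setGeneric("xVariates", function(object) standardGeneric("xVariates"))

#' @rdname accessors
#' @export
setGeneric("yVariates", function(object) standardGeneric("yVariates"))

#' @rdname accessors
#' @export
setGeneric("latentCor", function(object) standardGeneric("latentCor"))

#' @rdname accessors
#' @export
setGeneric("xMatrix", function(object) standardGeneric("xMatrix"))

#' @rdname accessors
#' @export
setGeneric("yMatrix", function(object) standardGeneric("yMatrix"))

#' @rdname accessors
#' @export
setGeneric("xCoords", function(object) standardGeneric("xCoords"))

#' @rdname accessors
#' @export
setGeneric("yCoords", function(object) standardGeneric("yCoords"))

#' @rdname accessors
#' @export
setGeneric("simMatrix", function(object) standardGeneric("simMatrix"))

#' @rdname accessors
#' @export
setGeneric("netNodes", function(object) standardGeneric("netNodes"))

#' @rdname accessors
#' @export
setGeneric("netEdges", function(object) standardGeneric("netEdges"))

#' @rdname accessors
#' @export
setGeneric("netThreshold", function(object) standardGeneric("netThreshold"))
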