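#' Build a Relevance Network from a similarity matrix
#'
#' Bipartite graph whose edges are the (X variable, Y variable) pairs with
#' |M_jk| >= threshold; the boundary is inclusive so that a printed
#' threshold such as 0.5 keeps an entry equal to 0.5. Variables without any
#' surviving edge are not represented.
#'
#' @param M a [SimilarityMatrix-class] (or plain numeric matrix with
#'   dimnames).
#' @param threshold absolute-value threshold in [0, 1].
#' @return a [RelevanceNetwork-class].
#' @examples
#' m <- matrix(c(0.7, 0.1, 0.55, -0.2, -0.9, 0), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("m", 1:2)))
#' relevanceNetwork(m, 0.5)
#' @export
relevanceNetwork <- function(M, threshold = 0.5) {
  m <- asSimMatrix(M)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  hit <- which(abs(m) >= threshold, arr.ind = TRUE)
  if (nrow(hit)) {
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    w <- m[hit]
    edges <- data.frame(
      x = rownames(m)[hit[, 1]],
      y = colnames(m)[hit[, 2]],
      weight = w,
      sign = ifelse(w >= 0, "+", "-"),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(x = character(), y = character(),
                        weight = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(
    id = c(rownames(m)[sort(unique(hit[, 1]))],
           colnames(m)[sort(unique(hit[, 2]))]),
    side = rep(c("X", "Y"),
               c(length(unique(hit[, 1])), length(unique(hit[, 2])))),
    stringsAsFactors = FALSE)
  new("RelevanceNetwork", nodes = nodes, edges = edges,
      threshold = threshold)
}

asSimMatrix <- function(M) {
  if (is(M, "SimilarityMatrix")) return(M@M)
  m <- as.matrix(M)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("X", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("Y", seq_len(ncol(m)))
  m
}

networkToIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("x", "y", "weight", "sign")],
    directed = FALSE, vertices = net@nodes)
  g
}

#' Connected components of a Relevance Network
#'
#' Standard undirected connected components; components are ordered by their
#' smallest member id and node ids are sorted within each component, so the
#' result is deterministic.
#'
#' @param net a [RelevanceNetwork-class].
#' @return list of character vectors of node ids (possibly empty).
#' @examples
#' m <- matrix(c(0.9, 0, 0, 0.8), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("m1", "m2")))
#' networkComponents(relevanceNetwork(m, 0.5))
#' @export
networkComponents <- function(net) {
  if (!is(net, "RelevanceNetwork"))
    stop("`net` must be a RelevanceNetwork")
  if (!nrow(net@nodes)) return(list())
  g <- networkToIgraph(net)
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, function(v) sort(v))
  parts[order(vapply(parts, function(v) v[1], character(1)))]
}

#' Export a Relevance Network to GraphML or SIF
#'
#' GraphML carries the node attribute `side` (X/Y) and edge attributes
#' `weight` and `sign`; a round-trip read reproduces the edge set exactly.
#' SIF writes one whitespace-delimited line per edge with interaction label
#' `pos` or `neg`.
#'
#' @param net a [RelevanceNetwork-class].
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- networkToIgraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- if (nrow(net@edges)) {
      paste(net@edges$x,
            ifelse(net@edges$sign == "+", "pos", "neg"),
            net@edges$y)
    } else character()
    writeLines(lines, path)
  }
  invisible(path)
}
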