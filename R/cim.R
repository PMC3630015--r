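#' Dual hierarchical clustering of a similarity matrix
#'
#' Clusters the rows of M on the distances between its row vectors and,
#' independently, the columns on the distances between its column vectors,
#' then reorders the matrix by the two dendrograms. The default follows the
#' common Clustered-Image-Map convention: Euclidean distance with Ward
#' linkage applied to the raw (non-squared) distances via the standard
#' Lance-Williams update ("ward.D" in base R terms).
#'
#' Leaf ordering within the constraints of each tree is deterministic: at
#' every merge the subtree with the lower merge height is placed first, ties
#' broken by smallest leaf index.
#'
#' @param M a [SimilarityMatrix-class] or plain matrix, at least 2 x 2.
#' @param distance `"euclidean"`, `"manhattan"` or `"maximum"`.
#' @param linkage `"ward"`, `"complete"`, `"average"` or `"single"`.
#' @return a [CIMResult-class].
#' @examples
#' m <- matrix(c(0.9, 0.8, 0, 0, 0, 0, 0.9, 0.85), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("m1", "m2")))
#' clusterSimilarity(m)@rowOrder
#' @export
clusterSimilarity <- function(M, distance = "euclidean", linkage = "ward") {
  m <- asSimMatrix(M)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("M must have at least 2 rows and 2 columns")
  dists <- c("euclidean", "manhattan", "maximum")
  links <- c(ward = "ward.D", complete = "complete", average = "average",
             single = "single")
  if (!distance %in% dists)
    stop("unknown distance '", distance, "'; use one of: ",
         paste(dists, collapse = ", "))
  if (!linkage %in% names(links))
    stop("unknown linkage '", linkage, "'; use one of: ",
         paste(names(links), collapse = ", "))
  hcRow <- stats::hclust(stats::dist(m, method = distance),
                         method = links[[linkage]])
  hcCol <- stats::hclust(stats::dist(t(m), method = distance),
                         method = links[[linkage]])
  hcRow$order <- orderLeaves(hcRow)
  hcCol$order <- orderLeaves(hcCol)
  new("CIMResult",
      matrix = m[hcRow$order, hcCol$order, drop = FALSE],
      rowOrder = as.integer(hcRow$order),
      colOrder = as.integer(hcCol$order),
      rowDend = hcRow, colDend = hcCol,
      distance = distance, linkage = linkage)
}

## Deterministic leaf order: recurse over the merge matrix; at each internal
## node place the child subtree with the smaller merge height first (leaves
## have height 0); break ties by the smallest leaf index contained.
orderLeaves <- function(hc) {
  merge <- hc$merge; height <- hc$height
  n <- nrow(merge) + 1L
  leaves <- vector("list", nrow(merge))
  info <- matrix(0, nrow(merge), 2)  # height, min leaf
  childLeaves <- function(k) if (k < 0) -k else leaves[[k]]
  childHeight <- function(k) if (k < 0) 0 else height[k]
  childMin <- function(k) if (k < 0) -k else info[k, 2]
  for (i in seq_len(nrow(merge))) {
    l <- merge[i, 1]; r <- merge[i, 2]
    hl <- childHeight(l); hr <- childHeight(r)
    first <- if (hl < hr) l else if (hr < hl) r else
      if (childMin(l) <= childMin(r)) l else r
    second <- if (identical(first, l)) r else l
    leaves[[i]] <- c(childLeaves(first), childLeaves(second))
    info[i, ] <- c(height[i], min(childMin(l), childMin(r)))
  }
  leaves[[nrow(merge)]]
}

#' Render a Clustered Image Map
#'
#' Heatmap of the reordered similarity matrix with the two dendrograms on
#' the top and left. The diverging colour scale is symmetric about zero and
#' saturates at +/-1 regardless of the empirical range of M, so the sign of
#' an association is always readable: green for positive, red for negative,
#' yellow near zero (a colour-blind-safe blue/white/red alternative is
#' available).
#'
#' @param result a [CIMResult-class] from [clusterSimilarity()].
#' @param file output file (`.png` or `.svg`); NULL draws on the active
#'   device.
#' @param palette `"green-red"` (default) or `"blue-red"`.
#' @param labels draw variable names along the axes.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return the file path (or NULL), invisibly.
#' @export
plotCIM <- function(result, file = NULL, palette = c("green-red", "blue-red"),
                    labels = TRUE, width = 900, height = 700) {
  if (!is(result, "CIMResult"))
    stop("`result` must be a CIMResult")
  palette <- match.arg(palette)
  cols <- if (palette == "green-red") {
    grDevices::colorRampPalette(c("#B2182B", "#F7F700", "#1B7837"))(201)
  } else {
    grDevices::colorRampPalette(c("#B2182B", "#F7F7F7", "#2166AC"))(201)
  }
  dev <- openDevice(file, width, height)
  on.exit(if (!is.null(dev)) grDevices::dev.off(), add = TRUE)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  m <- result@matrix
  graphics::layout(matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE),
                   widths = c(1, 4), heights = c(1, 4))
  ## top: column dendrogram
  graphics::par(mar = c(0.2, 0.5, 0.5, 0.5))
  plotDendrogramBare(result@colDend, horiz = FALSE)
  ## left: row dendrogram
  graphics::par(mar = c(2.5, 0.5, 0.2, 0.2))
  plotDendrogramBare(result@rowDend, horiz = TRUE)
  ## heatmap; image() draws row 1 at the bottom, matching the dendrogram
  ## leaf order of the horizontal tree on the left
  graphics::par(mar = c(2.5, 0.5, 0.2, 0.5))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m), zlim = c(-1, 1), col = cols, axes = FALSE,
                  xlab = "", ylab = "")
  if (labels) {
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                   las = 2, cex.axis = 0.5, tick = FALSE, line = -0.7)
    graphics::axis(4, at = seq_len(nrow(m)), labels = rownames(m),
                   las = 2, cex.axis = 0.5, tick = FALSE, line = -0.9)
  }
  graphics::box()
  invisible(file)
}

## dendrogram drawn without labels/axes so panels align with the heatmap
plotDendrogramBare <- function(hc, horiz) {
  d <- stats::as.dendrogram(hc)
  if (horiz) {
    graphics::plot(d, horiz = TRUE, leaflab = "none", yaxs = "i",
                   axes = FALSE, xlim = c(max(hc$height), 0))
  } else {
    graphics::plot(d, leaflab = "none", xaxs = "i", axes = FALSE)
  }
}

openDevice <- function(file, width, height) {
  if (is.null(file)) return(NULL)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              type = "cairo"),
         svg = grDevices::svg(file, width = width / 100,
                              height = height / 100),
         stop("unsupported image format '", ext, "'; use .png or .svg"))
  TRUE
}

#' Serialize a CIM clustering for downstream inspection
#'
#' Writes the permutations, merge trees and heights as JSON so a rendering
#' can be checked without parsing the image.
#'
#' @param result a [CIMResult-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeCIM <- function(result, path) {
  obj <- list(
    rowOrder = result@rowOrder,
    colOrder = result@colOrder,
    rowIds = rownames(result@matrix),
    colIds = colnames(result@matrix),
    rowMerge = result@rowDend$merge, rowHeight = result@rowDend$height,
    colMerge = result@colDend$merge, colHeight = result@colDend$height,
    distance = result@distance, linkage = result@linkage)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
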