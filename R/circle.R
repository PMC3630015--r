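#' Coordinates for a Correlation Circle plot
#'
#' Extracts the two requested dimensions of the variable coordinates as a
#' plotting table. Points lie inside the unit disk because every row of the
#' coordinate matrix is a vector of correlations with (near-)orthogonal
#' reference variates.
#'
#' @param coords a [VariableCoordinates-class].
#' @param dims two distinct dimension indices, both <= d.
#' @return data.frame with columns `id`, `side` ("X"/"Y"), `x`, `y`.
#' @examples
#' pd <- simulatePair(simulationDesign(), seed = 1)
#' co <- variableCoords(fitPLS(pd, 3, "canonical"), pd)
#' head(circleCoords(co, c(1, 2)))
#' @export
circleCoords <- function(coords, dims = c(1, 2)) {
  if (!is(coords, "VariableCoordinates"))
    stop("`coords` must be a VariableCoordinates object")
  dims <- as.integer(dims)
  if (length(dims) != 2L || dims[1] == dims[2])
    stop("dims must be two distinct dimension indices")
  if (any(dims < 1L) || any(dims > coords@d))
    stop(sprintf("dims must lie in [1, %d]", coords@d))
  tab <- rbind(
    data.frame(id = rownames(coords@x), side = "X",
               x = coords@x[, dims[1]], y = coords@x[, dims[2]],
               stringsAsFactors = FALSE),
    data.frame(id = rownames(coords@y), side = "Y",
               x = coords@y[, dims[1]], y = coords@y[, dims[2]],
               stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  r <- sqrt(tab$x^2 + tab$y^2)
  if (any(r > 1 + 1e-8))
    stop("coordinates fall outside the unit disk")
  attr(tab, "dims") <- dims
  tab
}

#' Render a Correlation Circle plot
#'
#' Scatter of the variables at the endpoints of their correlation vectors
#' for a chosen pair of dimensions, inside guide circles of radii 0.5 and 1.
#' X variables are drawn as filled points, Y variables as triangles. An
#' optional threshold hides points whose distance from the origin on the
#' displayed plane is below it, leaving the surviving positions untouched.
#'
#' @param coordTable a table from [circleCoords()] (or a
#'   [VariableCoordinates-class], in which case `dims` selects the plane).
#' @param file output `.png`/`.svg` path; NULL draws on the active device.
#' @param dims dimension pair, used when `coordTable` is a coordinate
#'   object.
#' @param threshold optional radius below which points are hidden.
#' @param labels draw variable ids next to the points.
#' @param width,height device size in pixels (png) or 1/100 inch (svg).
#' @return the file path (or NULL), invisibly.
#' @export
plotCircle <- function(coordTable, file = NULL, dims = c(1, 2),
                       threshold = NULL, labels = FALSE,
                       width = 700, height = 700) {
  if (is(coordTable, "VariableCoordinates"))
    coordTable <- circleCoords(coordTable, dims)
  else
    dims <- attr(coordTable, "dims") %||% dims
  if (!is.null(threshold)) {
    keep <- sqrt(coordTable$x^2 + coordTable$y^2) >= threshold
    coordTable <- coordTable[keep, , drop = FALSE]
  }
  dev <- openDevice(file, width, height)
  on.exit(if (!is.null(dev)) grDevices::dev.off(), add = TRUE)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::par(mar = c(4, 4, 1, 1), pty = "s")
  graphics::plot(NA, xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05),
                 xlab = paste("dimension", dims[1]),
                 ylab = paste("dimension", dims[2]), asp = 1)
  theta <- seq(0, 2 * pi, length.out = 361)
  for (r in c(0.5, 1))
    graphics::lines(r * cos(theta), r * sin(theta), col = "grey60")
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  if (nrow(coordTable)) {
    isX <- coordTable$side == "X"
    graphics::points(coordTable$x[isX], coordTable$y[isX], pch = 16,
                     col = "#D95F02", cex = 0.8)
    graphics::points(coordTable$x[!isX], coordTable$y[!isX], pch = 17,
                     col = "#1B9E77", cex = 0.8)
    if (labels)
      graphics::text(coordTable$x, coordTable$y, coordTable$id, pos = 3,
                     cex = 0.55)
  }
  graphics::legend("topright", legend = c("X", "Y"), pch = c(16, 17),
                   col = c("#D95F02", "#1B9E77"), bty = "n", cex = 0.8)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
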