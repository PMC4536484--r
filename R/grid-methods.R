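## Accessors, show methods and coordinate arithmetic for the raster classes.

#' @rdname EnvironmentGrid-class
#' @param object,x an object.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname EnvironmentGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname EnvironmentGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname EnvironmentGrid-class
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname EnvironmentGrid-class
#' @param name layer name.
#' @export
setGeneric("gridLayer", function(x, name) standardGeneric("gridLayer"))

#' @rdname EnvironmentGrid-class
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))

#' @rdname GridLayer-class
#' @param x an object.
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))

#' @rdname GridLayer-class
#' @export
setGeneric("flaggedCells", function(x) standardGeneric("flaggedCells"))

setMethod("gridDim", "EnvironmentGrid", function(x) dim(x@layers[[1L]]))
setMethod("gridDim", "GridLayer", function(x) dim(x@values))
setMethod("cellSize", "EnvironmentGrid", function(x) x@cellSize)
setMethod("cellSize", "GridLayer", function(x) x@cellSize)
setMethod("gridOrigin", "EnvironmentGrid", function(x) x@origin)
setMethod("gridOrigin", "GridLayer", function(x) x@origin)
setMethod("layerNames", "EnvironmentGrid", function(x) names(x@layers))
setMethod("validityMask", "EnvironmentGrid", function(x) x@mask)
setMethod("layerValues", "GridLayer", function(x) x@values)
setMethod("flaggedCells", "GridLayer", function(x) x@flagged)

setMethod("gridLayer", "EnvironmentGrid", function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer '", name, "'; available: ",
         paste(names(x@layers), collapse = ", "), call. = FALSE)
  out <- x@layers[[name]]
  out[!x@mask] <- NA_real_
  out
})

#' @rdname EnvironmentGrid-class
#' @param i layer name (character).
#' @export
setMethod("[[", "EnvironmentGrid", function(x, i) gridLayer(x, i))

setMethod("show", "EnvironmentGrid", function(object) {
  d <- gridDim(object)
  cat("EnvironmentGrid:", d[1L], "x", d[2L], "cells @", object@cellSize,
      "m\n  layers:", paste(names(object@layers), collapse = ", "),
      "\n  valid cells:", sum(object@mask), "/", length(object@mask), "\n")
  dp <- gridLayer(object, names(object@layers)[1L])
  rng <- range(dp, na.rm = TRUE)
  cat("  ", names(object@layers)[1L], " range: [",
      signif(rng[1L], 4), ", ", signif(rng[2L], 4), "]\n", sep = "")
})

setMethod("show", "GridLayer", function(object) {
  d <- dim(object@values)
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  cat(class(object), ":", d[1L], "x", d[2L], "cells @", object@cellSize,
      "m\n  value range: [", signif(rng[1L], 4), ",", signif(rng[2L], 4),
      "]  flagged:", sum(object@flagged), "\n")
})

setMethod("show", "TerrainLayer", function(object) {
  callNextMethod()
  cat("  metric:", object@metric, " method:", object@method,
      " window:", object@window, "\n")
})

setMethod("show", "ErrorRaster", function(object) {
  callNextMethod()
  cat("  scaleBasis:", signif(object@scaleBasis, 5), " variogram:",
      object@variogram$model, "(nugget", signif(object@variogram$nugget, 4),
      ", sill", signif(object@variogram$sill, 4),
      ", range", signif(object@variogram$range, 5), ")\n")
})

## ---- coordinate <-> index arithmetic ---------------------------------------
## 0-based row-major indexing internally documented; R matrices are 1-based.
## Origin is the centre of cell (1,1); x grows with columns (east), y shrinks
## with rows (south). Cell boundaries are half-open: a point on the shared
## edge of two cells belongs to the cell with the larger index.

cellCenters <- function(dim, cellSize, origin) {
  x <- origin[1L] + (seq_len(dim[2L]) - 1L) * cellSize
  y <- origin[2L] - (seq_len(dim[1L]) - 1L) * cellSize
  list(x = x, y = y)
}

pointToCell <- function(points, dim, cellSize, origin) {
  px <- points[, 1L]; py <- points[, 2L]
  col <- floor((px - origin[1L] + cellSize / 2) / cellSize) + 1L
  row <- floor((origin[2L] + cellSize / 2 - py) / cellSize) + 1L
  inside <- col >= 1L & col <= dim[2L] & row >= 1L & row <= dim[1L]
  cbind(row = row, col = col, inside = inside)
}

#' Extract raster values at point locations
#'
#' Nearest-cell extraction (no interpolation): each point is assigned the
#' cell whose centre is nearest, with half-open cell boundaries. Points on
#' masked/nodata cells yield `NA`; points outside the grid extent raise an
#' error listing the offenders.
#'
#' @param x an [EnvironmentGrid-class], [GridLayer-class] or plain numeric
#'   matrix.
#' @param points two-column matrix or data.frame of planar `(x, y)`
#'   coordinates, metres.
#' @param ... passed on; for matrices, supply `cellSize` and `origin`.
#' @return for a grid, a data.frame with one column per layer; for a single
#'   layer, a numeric vector.
#' @export
setGeneric("sampleAtPoints", function(x, points, ...)
  standardGeneric("sampleAtPoints"))

sampleMatrixAtPoints <- function(values, points, cellSize, origin) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  idx <- pointToCell(points, dim(values), cellSize, origin)
  if (any(!idx[, "inside"])) {
    bad <- which(!idx[, "inside"])
    stop("points outside grid extent: rows ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  values[cbind(idx[, "row"], idx[, "col"])]
}

#' @rdname sampleAtPoints
setMethod("sampleAtPoints", "EnvironmentGrid", function(x, points, ...) {
  out <- lapply(names(x@layers), function(nm)
    sampleMatrixAtPoints(gridLayer(x, nm), points, x@cellSize, x@origin))
  names(out) <- names(x@layers)
  as.data.frame(out)
})

#' @rdname sampleAtPoints
setMethod("sampleAtPoints", "GridLayer", function(x, points, ...)
  sampleMatrixAtPoints(x@values, points, x@cellSize, x@origin))

#' @rdname sampleAtPoints
#' @param cellSize,origin grid geometry when `x` is a bare matrix.
setMethod("sampleAtPoints", "matrix",
  function(x, points, cellSize, origin = c(0, 0), ...)
    sampleMatrixAtPoints(x, points, cellSize, origin))

## constructor used across modules
newEnvironmentGrid <- function(layers, cellSize, origin = c(0, 0),
                               mask = NULL) {
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(layers[[1L]]), ncol(layers[[1L]]))
  new("EnvironmentGrid", layers = layers, cellSize = cellSize,
      origin = as.numeric(origin), mask = mask)
}
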