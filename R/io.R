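## Plain-text exchange formats: ESRI ASCII grids for rasters (one file per
## layer) and CSV for survey tables. The ASCII grid is the package's raster
## exchange format; inputs are assumed already projected to a planar
## equal-area grid.

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param x numeric matrix, [GridLayer-class] or a single layer name of an
#'   [EnvironmentGrid-class] via [writeEnvironmentGrid()].
#' @param path output `.asc` path.
#' @param cellSize,origin grid geometry for bare matrices (origin = centre
#'   of the top-left cell).
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
writeAsciiGrid <- function(x, path, cellSize = NULL, origin = c(0, 0),
                           nodata = -9999) {
  if (is(x, "GridLayer")) {
    cellSize <- x@cellSize; origin <- x@origin; x <- x@values
  }
  stopifnot(is.matrix(x), !is.null(cellSize))
  nr <- nrow(x); nc <- ncol(x)
  hdr <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(origin[1L] - cellSize / 2, scientific = FALSE)),
    paste("yllcorner", format(origin[2L] + cellSize / 2 - nr * cellSize,
                              scientific = FALSE)),
    paste("cellsize", format(cellSize, scientific = FALSE)),
    paste("NODATA_value", nodata))
  vals <- x
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1L, function(row)
    paste(format(row, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @return list: `values` (matrix, `NA` for nodata), `cellSize`, `origin`
#'   (top-left cell centre).
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- matrix(scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                      quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  origin <- c(hdr$xllcorner + hdr$cellsize / 2,
              hdr$yllcorner + nr * hdr$cellsize - hdr$cellsize / 2)
  list(values = vals, cellSize = hdr$cellsize, origin = origin)
}

#' Write / read an environment grid as a directory of ASCII grids
#'
#' One `<layer>.asc` per layer plus `mask.asc` (1 = valid sea cell).
#'
#' @param env an [EnvironmentGrid-class].
#' @param dir directory (created if needed).
#' @export
writeEnvironmentGrid <- function(env, dir) {
  stopifnot(is(env, "EnvironmentGrid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(env@layers))
    writeAsciiGrid(env@layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                   env@cellSize, env@origin)
  writeAsciiGrid(matrix(as.numeric(env@mask), nrow(env@mask)),
                 file.path(dir, "mask.asc"), env@cellSize, env@origin)
  invisible(dir)
}

#' @rdname writeEnvironmentGrid
#' @param layers layer names to read (default the five predictors).
#' @export
readEnvironmentGrid <- function(dir, layers = predictorNames()) {
  reads <- lapply(layers, function(nm)
    readAsciiGrid(file.path(dir, paste0(nm, ".asc"))))
  maskPath <- file.path(dir, "mask.asc")
  mask <- if (file.exists(maskPath)) {
    readAsciiGrid(maskPath)$values == 1
  } else NULL
  newEnvironmentGrid(setNames(lapply(reads, `[[`, "values"), layers),
                     cellSize = reads[[1L]]$cellSize,
                     origin = reads[[1L]]$origin, mask = mask)
}

#' Survey table CSV round trip
#'
#' Column dictionary: `station_id` (character), `x`, `y` (planar metres),
#' `year` (replication index), `stratum` (1-based depth-stratum index),
#' the five predictors (`depth` m, `slope` degrees, `rugosity` \[0,1\],
#' `salinity` PSU, `sst` deg C), `density_<species>` (N km^-2),
#' `presence_<species>` (0/1, equals `density > 0`), `richness` (count of
#' species with positive density).
#'
#' @param survey survey table.
#' @param path CSV path.
#' @export
writeSurveyCsv <- function(survey, path) {
  write.csv(survey, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurveyCsv
#' @export
readSurveyCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
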