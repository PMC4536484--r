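## Bathymetry-derived terrain predictors: slope (degrees, Horn's method) and
## rugosity (vector ruggedness measure, or a normalised surface/planar area
## ratio). Both operate on a depth matrix in metres (positive down); both are
## invariant to adding a constant to the depth surface, and rugosity is
## reported on [0, 1] (0 = no terrain variation).

## 3x3 Horn gradient with NA/boundary fallback: missing or off-grid
## neighbours are replaced by the centre value (available-neighbour
## fallback) and the cell is flagged as computed from a truncated window.
hornGradient <- function(z, cellSize) {
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("raster must be at least 3x3", call. = FALSE)
  if (all(is.na(z))) stop("all-nodata raster", call. = FALSE)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- z
  shift <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  nbr <- list(nw = shift(-1L, -1L), n = shift(-1L, 0L), ne = shift(-1L, 1L),
              w  = shift(0L, -1L),                     e  = shift(0L, 1L),
              sw = shift(1L, -1L),  s = shift(1L, 0L), se = shift(1L, 1L))
  flagged <- Reduce(`|`, lapply(nbr, is.na))
  flagged[is.na(z)] <- FALSE              # nodata centres stay NA, not flagged
  nbr <- lapply(nbr, function(m) ifelse(is.na(m), z, m))
  gx <- ((nbr$ne + 2 * nbr$e + nbr$se) - (nbr$nw + 2 * nbr$w + nbr$sw)) /
    (8 * cellSize)
  gy <- ((nbr$sw + 2 * nbr$s + nbr$se) - (nbr$nw + 2 * nbr$n + nbr$ne)) /
    (8 * cellSize)
  list(gx = gx, gy = gy, flagged = flagged)
}

#' Seafloor slope in degrees from a depth raster
#'
#' Rate of change of elevation over distance: per-cell slope =
#' `atan(||grad z||)` in degrees (0 = flat, 90 = vertical), with the
#' gradient estimated by Horn's 3x3 weighted finite differences. Cells whose
#' 3x3 window is truncated by the grid boundary or by nodata neighbours fall
#' back to the available neighbours and are flagged; flagged cells are
#' excluded from model fitting by default downstream.
#'
#' @param depth numeric matrix of depths (metres, positive down) or an
#'   [EnvironmentGrid-class] with a `depth` layer.
#' @param cellSize cell side length in metres (taken from the grid when
#'   `depth` is an [EnvironmentGrid-class]).
#' @return a [TerrainLayer-class] with `metric = "slope_degrees"`.
#' @examples
#' computeSlope(matrix(200, 8, 8), cellSize = 866)  # flat seafloor: 0 degrees
#' @export
computeSlope <- function(depth, cellSize = NULL) {
  geom <- resolveDepthInput(depth, cellSize)
  g <- hornGradient(geom$z, geom$cellSize)
  slope <- atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi
  slope[is.na(geom$z)] <- NA_real_
  new("TerrainLayer", values = slope, cellSize = geom$cellSize,
      origin = geom$origin, flagged = g$flagged, metric = "slope_degrees",
      method = "horn", window = 3L)
}

#' Seafloor rugosity (terrain complexity) on \[0, 1\]
#'
#' Terrain-complexity indicator of the bumpiness of the seafloor, reported
#' on \[0, 1\] (0 = no terrain variation; natural terrains rarely exceed
#' ~0.4). Two variants:
#'
#' * `"vrm"` (default): vector ruggedness measure — the per-cell unit
#'   normals of the depth surface are summed over the window and rugosity is
#'   `1 - ||sum|| / n`; 0 when all normals are parallel (flat or uniformly
#'   inclined terrain), approaching 1 for fully dispersed normals.
#' * `"area_ratio_normalised"`: `1 - planar area / triangulated surface
#'   area` over the window, in \[0, 1); 0 on flat terrain.
#'
#' Boundary or nodata-truncated windows are flagged.
#'
#' @inheritParams computeSlope
#' @param method `"vrm"` or `"area_ratio_normalised"`.
#' @param window odd neighbourhood size in cells (default 3).
#' @return a [TerrainLayer-class] with `metric = "rugosity"`.
#' @export
computeRugosity <- function(depth, cellSize = NULL,
                            method = c("vrm", "area_ratio_normalised"),
                            window = 3L) {
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  geom <- resolveDepthInput(depth, cellSize)
  vals <- switch(method,
    vrm = rugosityVrm(geom$z, geom$cellSize, window),
    area_ratio_normalised = rugosityAreaRatio(geom$z, geom$cellSize, window))
  new("TerrainLayer", values = vals$values, cellSize = geom$cellSize,
      origin = geom$origin, flagged = vals$flagged, metric = "rugosity",
      method = method, window = window)
}

rugosityVrm <- function(z, cellSize, window) {
  g <- hornGradient(z, cellSize)
  nrm <- sqrt(g$gx^2 + g$gy^2 + 1)
  nx <- -g$gx / nrm; ny <- -g$gy / nrm; nz <- 1 / nrm
  half <- (window - 1L) %/% 2L
  nr <- nrow(z); nc <- ncol(z)
  sx <- matrix(0, nr, nc); sy <- sx; sz <- sx; cnt <- sx
  trunc <- g$flagged
  for (dr in -half:half) for (dc in -half:half) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    off <- (seq_len(nr) + dr < 1L) | (seq_len(nr) + dr > nr)
    offc <- (seq_len(nc) + dc < 1L) | (seq_len(nc) + dc > nc)
    vx <- nx[rs, cs, drop = FALSE]; vy <- ny[rs, cs, drop = FALSE]
    vz <- nz[rs, cs, drop = FALSE]
    ok <- !is.na(vx)
    ## window members that fall off-grid or on nodata: dropped + flagged
    trunc <- trunc | outer(off, rep(TRUE, nc)) | outer(rep(TRUE, nr), offc) |
      !ok | g$flagged[rs, cs, drop = FALSE]
    vx[!ok] <- 0; vy[!ok] <- 0; vz[!ok] <- 0
    offgrid <- outer(off, rep(TRUE, nc)) | outer(rep(TRUE, nr), offc)
    vx[offgrid] <- 0; vy[offgrid] <- 0; vz[offgrid] <- 0
    ok[offgrid] <- FALSE
    sx <- sx + vx; sy <- sy + vy; sz <- sz + vz; cnt <- cnt + ok
  }
  vrm <- 1 - sqrt(sx^2 + sy^2 + sz^2) / pmax(cnt, 1)
  vrm <- pmin(pmax(vrm, 0), 1)
  vrm[is.na(z)] <- NA_real_
  list(values = vrm, flagged = trunc & !is.na(z))
}

## surface area of the window's depth surface by explicit triangulation:
## each cell of the window's point lattice split into two triangles.
rugosityAreaRatio <- function(z, cellSize, window) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  flagged <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c])) next
    r0 <- max(1L, r - half); r1 <- min(nr, r + half)
    c0 <- max(1L, c - half); c1 <- min(nc, c + half)
    sub <- z[r0:r1, c0:c1, drop = FALSE]
    truncated <- (r1 - r0 + 1L) < window || (c1 - c0 + 1L) < window ||
      anyNA(sub)
    if (anyNA(sub)) sub[is.na(sub)] <- z[r, c]   # available-value fallback
    if (nrow(sub) < 2L || ncol(sub) < 2L) { flagged[r, c] <- TRUE; next }
    surf <- triangulatedArea(sub, cellSize)
    plan <- (nrow(sub) - 1L) * (ncol(sub) - 1L) * cellSize^2
    out[r, c] <- min(max(1 - plan / surf, 0), 1)
    flagged[r, c] <- truncated
  }
  list(values = out, flagged = flagged)
}

triangulatedArea <- function(sub, cellSize) {
  area <- 0
  for (i in seq_len(nrow(sub) - 1L)) for (j in seq_len(ncol(sub) - 1L)) {
    p00 <- c(0, 0, sub[i, j]);            p01 <- c(cellSize, 0, sub[i, j + 1L])
    p10 <- c(0, cellSize, sub[i + 1L, j]); p11 <- c(cellSize, cellSize, sub[i + 1L, j + 1L])
    area <- area + triArea(p00, p01, p10) + triArea(p01, p11, p10)
  }
  area
}

triArea <- function(a, b, c) {
  u <- b - a; v <- c - a
  w <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  0.5 * sqrt(sum(w^2))
}

resolveDepthInput <- function(depth, cellSize) {
  if (is(depth, "EnvironmentGrid")) {
    list(z = gridLayer(depth, "depth"), cellSize = depth@cellSize,
         origin = depth@origin)
  } else {
    if (is.null(cellSize) || cellSize <= 0)
      stop("cellSize must be a positive number", call. = FALSE)
    list(z = as.matrix(depth), cellSize = cellSize, origin = c(0, 0))
  }
}
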