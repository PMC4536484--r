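#' @import methods
#' @importFrom stats coef cor dist lm logLik median optim pchisq pnbinom
#'   predict pt qnbinom quantile rbinom rnorm runif sd setNames var rank
#' @importFrom utils read.csv write.csv head
NULL

## ---- raster-like containers -------------------------------------------------

#' Virtual base class for single-layer planar rasters
#'
#' Holds a numeric matrix of per-cell values on a regular planar grid, with
#' the grid geometry (square cell size in metres, origin at the *centre* of
#' the top-left cell, rows increasing southwards) and a logical matrix
#' flagging cells whose value was computed from a truncated neighbourhood
#' (grid boundary or nodata-adjacent).
#'
#' @slot values numeric matrix of cell values (`NA` = nodata).
#' @slot cellSize side length of a square cell, metres.
#' @slot origin numeric length-2, planar `(x, y)` of the top-left cell centre.
#' @slot flagged logical matrix, `TRUE` where the value comes from a
#'   truncated window and should be excluded from model fitting by default.
#' @name GridLayer-class
#' @aliases GridLayer
#' @exportClass GridLayer
setClass("GridLayer",
  representation("VIRTUAL",
    values  = "matrix",
    cellSize = "numeric",
    origin  = "numeric",
    flagged = "matrix"
  )
)

validGridLayer <- function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be length-2 (x, y)")
  if (!identical(dim(object@values), dim(object@flagged)))
    msg <- c(msg, "values and flagged must share dimensions")
  if (length(msg)) msg else TRUE
}

#' Bathymetry-derived terrain layer (slope or rugosity)
#'
#' @slot metric `"slope_degrees"` or `"rugosity"`.
#' @slot method for rugosity, `"vrm"` or `"area_ratio_normalised"`;
#'   `"horn"` for slope.
#' @slot window neighbourhood size in cells (odd, default 3).
#' @name TerrainLayer-class
#' @aliases TerrainLayer
#' @exportClass TerrainLayer
setClass("TerrainLayer",
  contains = "GridLayer",
  representation(metric = "character", method = "character",
                 window = "integer"),
  validity = function(object) {
    msg <- character()
    v <- validGridLayer(object)
    if (!isTRUE(v)) msg <- c(msg, v)
    if (!object@metric %in% c("slope_degrees", "rugosity"))
      msg <- c(msg, "metric must be 'slope_degrees' or 'rugosity'")
    ok <- object@values[!is.na(object@values)]
    if (object@metric == "slope_degrees" && length(ok) &&
        (min(ok) < -1e-9 || max(ok) > 90 + 1e-9))
      msg <- c(msg, "slope values must lie in [0, 90] degrees")
    if (object@metric == "rugosity" && length(ok) &&
        (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
      msg <- c(msg, "rugosity values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Model-prediction raster
#'
#' @slot mode `"delta"` (density, N km^-2), `"occurrence"` (probability) or
#'   `"positive"` (conditional density).
#' @slot extrapolated logical matrix; `TRUE` where a predictor value lies
#'   outside the fitted model's training range.
#' @name PredictionRaster-class
#' @aliases PredictionRaster
#' @exportClass PredictionRaster
setClass("PredictionRaster",
  contains = "GridLayer",
  representation(mode = "character", extrapolated = "matrix"),
  validity = function(object) {
    msg <- character()
    v <- validGridLayer(object)
    if (!isTRUE(v)) msg <- c(msg, v)
    ok <- object@values[!is.na(object@values)]
    if (length(ok) && min(ok) < -1e-9)
      msg <- c(msg, "predictions must be nonnegative")
    if (object@mode == "occurrence" && length(ok) && max(ok) > 1 + 1e-9)
      msg <- c(msg, "occurrence probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Kriged, 0-1 scaled model-error raster
#'
#' Cell values are ordinary-kriging interpolations of per-station absolute
#' prediction errors, clipped at zero and divided by the maximum observed
#' absolute error (`scaleBasis`), so 1 marks the largest prediction error.
#'
#' @slot variogram fitted variogram model (list: `model`, `nugget`,
#'   `psill`, `sill`, `range`).
#' @slot scaleBasis the maximum absolute error used for scaling.
#' @name ErrorRaster-class
#' @aliases ErrorRaster
#' @exportClass ErrorRaster
setClass("ErrorRaster",
  contains = "GridLayer",
  representation(variogram = "list", scaleBasis = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- validGridLayer(object)
    if (!isTRUE(v)) msg <- c(msg, v)
    ok <- object@values[!is.na(object@values)]
    if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
      msg <- c(msg, "scaled error values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Aligned multi-layer environmental raster stack
#'
#' The prediction domain and sampling frame: five co-registered layers
#' (`depth` in positive metres below the surface, `slope` in degrees,
#' `rugosity` dimensionless in \[0,1\], `salinity` in PSU, `sst` in deg C)
#' plus a validity mask separating sea cells from land/out-of-domain cells.
#' Masked cells propagate as `NA` through every per-cell operation.
#'
#' @slot layers named list of numeric matrices, identical dimensions.
#' @slot cellSize square cell side, metres.
#' @slot origin planar `(x, y)` of the top-left cell centre.
#' @slot mask logical matrix, `TRUE` = valid sea cell.
#' @name EnvironmentGrid-class
#' @aliases EnvironmentGrid
#' @exportClass EnvironmentGrid
setClass("EnvironmentGrid",
  representation(layers = "list", cellSize = "numeric", origin = "numeric",
                 mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!length(object@layers) || is.null(names(object@layers)) ||
        any(!nzchar(names(object@layers))))
      msg <- c(msg, "layers must be a non-empty named list")
    dims <- unique(lapply(object@layers, dim))
    if (length(dims) > 1L)
      msg <- c(msg, "all layers must share identical dimensions")
    if (length(dims) == 1L && !identical(dims[[1L]], dim(object@mask)))
      msg <- c(msg, "mask must match layer dimensions")
    if (length(object@cellSize) != 1L || object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    sl <- object@layers[["slope"]]
    if (!is.null(sl)) {
      ok <- sl[!is.na(sl)]
      if (length(ok) && (min(ok) < -1e-9 || max(ok) > 90 + 1e-9))
        msg <- c(msg, "slope layer must lie in [0, 90]")
    }
    rg <- object@layers[["rugosity"]]
    if (!is.null(rg)) {
      ok <- rg[!is.na(rg)]
      if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
        msg <- c(msg, "rugosity layer must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

## ---- survey-side containers -------------------------------------------------

#' Synthetic species-environment truth
#'
#' A known data-generating relationship used to simulate surveys and to
#' score model recovery: an occurrence response \eqn{p(\cdot) \in [0,1]}, a
#' positive-abundance response \eqn{\mu(\cdot) > 0} (mean density, N km^-2),
#' and a negative-binomial dispersion (size) parameter. Predictors outside
#' `activePredictors` have exactly zero effect.
#'
#' @slot speciesId character identifier.
#' @slot occurrence function(data.frame of predictors) -> probability vector.
#' @slot abundance function(data.frame of predictors) -> positive mean density.
#' @slot dispersion negative-binomial size parameter k > 0.
#' @slot activePredictors character subset of
#'   `c("depth","slope","rugosity","salinity","sst")`.
#' @slot shapes the shape specifications the responses were built from.
#' @name SpeciesTruth-class
#' @aliases SpeciesTruth
#' @exportClass SpeciesTruth
setClass("SpeciesTruth",
  representation(speciesId = "character", occurrence = "function",
                 abundance = "function", dispersion = "numeric",
                 activePredictors = "character", shapes = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@dispersion) != 1L || object@dispersion <= 0)
      msg <- c(msg, "dispersion (NB size) must be a single positive number")
    bad <- setdiff(object@activePredictors, predictorNames())
    if (length(bad))
      msg <- c(msg, paste0("unknown predictors: ", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)

#' Depth-stratified random survey design
#'
#' @slot strata two-column numeric matrix of depth interval bounds in metres;
#'   the first stratum is closed `[lower, upper]`, subsequent strata are
#'   half-open `(lower, upper]`, removing boundary double-assignment.
#' @slot nStations total stations per survey year, allocated to strata
#'   proportionally to stratum area (largest-remainder rounding).
#' @slot sweptArea swept area per haul, km^2 (scalar).
#' @name SurveyDesign-class
#' @aliases SurveyDesign
#' @exportClass SurveyDesign
setClass("SurveyDesign",
  representation(strata = "matrix", nStations = "integer",
                 sweptArea = "numeric"),
  validity = function(object) {
    msg <- character()
    s <- object@strata
    if (ncol(s) != 2L || any(s[, 2L] <= s[, 1L]))
      msg <- c(msg, "strata must be a 2-column matrix with upper > lower")
    if (nrow(s) > 1L && any(s[-1L, 1L] < s[-nrow(s), 2L]))
      msg <- c(msg, "strata must be ordered and non-overlapping")
    if (object@nStations < 1L)
      msg <- c(msg, "nStations must be >= 1")
    if (any(object@sweptArea <= 0))
      msg <- c(msg, "sweptArea must be positive")
    if (length(msg)) msg else TRUE
  }
)

## ---- model containers -------------------------------------------------------

#' One component of a delta model
#'
#' Either the binomial-logit occurrence part or the negative-binomial
#' log-link positive-abundance part, with each term entering as a univariate
#' penalized cubic regression spline smooth.
#'
#' @slot part `"occurrence"` or `"positive"`.
#' @slot response name of the response column modelled.
#' @slot family `"binomial-logit"` or `"negative-binomial-log"`.
#' @slot terms predictor names with fitted smooths (may be empty:
#'   intercept-only).
#' @slot fit the underlying [mgcv::gam()] object.
#' @slot n observations used.
#' @slot logLik maximized log-likelihood.
#' @slot edf total effective degrees of freedom (incl. intercept, plus one
#'   for an estimated NB dispersion).
#' @slot devianceExplained percent deviance explained, \[0, 100\].
#' @slot adjR2 adjusted r-squared.
#' @slot trainRanges per-term numeric range seen at fit time (extrapolation
#'   flagging).
#' @name ComponentFit-class
#' @aliases ComponentFit
#' @exportClass ComponentFit
setClass("ComponentFit",
  representation(part = "character", response = "character",
                 family = "character", terms = "character", fit = "ANY",
                 n = "integer", logLik = "numeric", edf = "numeric",
                 devianceExplained = "numeric", adjR2 = "numeric",
                 trainRanges = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@part %in% c("occurrence", "positive"))
      msg <- c(msg, "part must be 'occurrence' or 'positive'")
    if (is.finite(object@devianceExplained) &&
        (object@devianceExplained < -1e-6 || object@devianceExplained > 100 + 1e-6))
      msg <- c(msg, "devianceExplained must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted delta (hurdle) model
#'
#' Pairs a binomial occurrence component with a positive-abundance component
#' fitted on the strictly positive subset of the same data; final predictions
#' multiply the two. `mode = "binomial_only"` carries the occurrence part
#' alone, used when the delta model's evaluation is poor.
#'
#' @slot occurrence [ComponentFit-class] for presence/absence.
#' @slot positive [ComponentFit-class] for positive densities, or `NULL`.
#' @slot mode `"delta"` or `"binomial_only"`.
#' @name HurdleFit-class
#' @aliases HurdleFit
#' @exportClass HurdleFit
setClass("HurdleFit",
  representation(occurrence = "ComponentFit", positive = "ANY",
                 mode = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("delta", "binomial_only"))
      msg <- c(msg, "mode must be 'delta' or 'binomial_only'")
    if (object@mode == "delta" && !is(object@positive, "ComponentFit"))
      msg <- c(msg, "mode 'delta' requires a fitted positive component")
    if (length(msg)) msg else TRUE
  }
)

#' Candidate models ranked by AICc
#'
#' @slot table data.frame, one row per candidate: term flags, effective
#'   parameters `k`, `logLik`, `AICc`, `deltaAICc`, `weight`,
#'   `devExplained`, `adjR2`, `fitted` (logical), `error` (message or "").
#' @slot bestIndex row index of the best-supported (lowest-AICc) model.
#' @slot competing row indices with `deltaAICc <= 2` (always contains best).
#' @slot part,response which component / response the candidates model.
#' @slot bestFit the refitted best candidate ([ComponentFit-class]).
#' @name SelectionTable-class
#' @aliases SelectionTable
#' @exportClass SelectionTable
setClass("SelectionTable",
  representation(table = "data.frame", bestIndex = "integer",
                 competing = "integer", part = "character",
                 response = "character", bestFit = "ANY"),
  validity = function(object) {
    msg <- character()
    tb <- object@table
    if (!nrow(tb)) return("empty candidate table")
    ok <- which(tb$fitted)
    if (!length(ok)) return("no candidate fitted successfully")
    if (abs(tb$AICc[object@bestIndex] - min(tb$AICc[ok])) > 1e-8)
      msg <- c(msg, "bestIndex must attain the minimum AICc")
    if (!object@bestIndex %in% object@competing)
      msg <- c(msg, "competing set must contain the best model")
    w <- tb$weight[ok]
    if (abs(sum(w) - 1) > 1e-8)
      msg <- c(msg, "Akaike weights must sum to 1 over fitted candidates")
    if (length(msg)) msg else TRUE
  }
)

#' The five canonical environmental predictors
#'
#' `depth` (m), `slope` (degrees), `rugosity` (\[0,1\]), `salinity` (PSU)
#' and `sst` (deg C) — the predictor set the habitat models draw terms
#' from.
#'
#' @return character vector of predictor names.
#' @export
predictorNames <- function() c("depth", "slope", "rugosity", "salinity", "sst")
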