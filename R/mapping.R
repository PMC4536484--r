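## Prediction rasters over the environment grid, empirical-variogram
## fitting, ordinary kriging, and the 0-1 scaled kriged model-error
## surfaces used to illustrate prediction uncertainty.

#' Predict a fitted model over an environment grid
#'
#' Evaluates the delta model (or a single component) at every unmasked cell
#' of the grid; the delta raster is exactly the elementwise product of the
#' occurrence and positive component rasters. Cells whose predictor values
#' fall outside the training range are flagged in the `extrapolated`
#' sidecar matrix.
#'
#' @param fit a [HurdleFit-class] or [ComponentFit-class].
#' @param env an [EnvironmentGrid-class] supplying all fitted terms.
#' @return a [PredictionRaster-class].
#' @export
predictRaster <- function(fit, env) {
  stopifnot(is(env, "EnvironmentGrid"))
  if (is(fit, "HurdleFit") && fit@mode == "delta") {
    po <- predictRaster(fit@occurrence, env)
    pp <- predictRaster(fit@positive, env)
    return(new("PredictionRaster", values = po@values * pp@values,
               cellSize = env@cellSize, origin = env@origin,
               flagged = po@flagged, mode = "delta",
               extrapolated = po@extrapolated | pp@extrapolated))
  }
  if (is(fit, "HurdleFit")) fit <- fit@occurrence
  stopifnot(is(fit, "ComponentFit"))
  miss <- setdiff(fit@terms, names(env@layers))
  if (length(miss))
    stop("grid lacks layers: ", paste(miss, collapse = ", "), call. = FALSE)
  dims <- gridDim(env)
  nd <- as.data.frame(lapply(env@layers, as.vector))
  keep <- as.vector(env@mask)
  vals <- rep(NA_real_, prod(dims))
  pr <- predictComponent(fit, nd[keep, , drop = FALSE])
  vals[keep] <- as.numeric(pr)
  ex <- rep(FALSE, prod(dims))
  ex[keep] <- attr(pr, "extrapolated")
  new("PredictionRaster", values = matrix(vals, dims[1L], dims[2L]),
      cellSize = env@cellSize, origin = env@origin,
      flagged = matrix(FALSE, dims[1L], dims[2L]),
      mode = fit@part,
      extrapolated = matrix(ex, dims[1L], dims[2L]))
}

## semivariogram model evaluation
variogramValue <- function(model, h) {
  with(model, switch(model,
    nugget = ifelse(h > 0, nugget, 0),
    spherical = ifelse(h <= 0, 0,
      ifelse(h < range, nugget + psill * (1.5 * h / range -
                                          0.5 * (h / range)^3),
             nugget + psill)),
    exponential = ifelse(h <= 0, 0,
      nugget + psill * (1 - exp(-3 * h / range))),
    stop("unknown variogram model '", model, "'", call. = FALSE)))
}

empiricalVariogram <- function(coords, values, nBins = 12,
                               maxLagFrac = 0.5) {
  D <- as.matrix(dist(coords))
  iu <- upper.tri(D)
  d <- D[iu]
  g <- 0.5 * outer(values, values, `-`)[iu]^2
  maxLag <- maxLagFrac * max(d)
  keep <- d <= maxLag & d > 0
  d <- d[keep]; g <- g[keep]
  brk <- seq(0, max(d), length.out = nBins + 1)
  cl <- findInterval(d, brk, rightmost.closed = TRUE, all.inside = TRUE)
  cf <- factor(cl)
  data.frame(
    dist = as.numeric(rowsum(d, cf)) / as.numeric(table(cf)),
    gamma = as.numeric(rowsum(g, cf)) / as.numeric(table(cf)),
    npairs = as.numeric(table(cf)))
}

fitVariogramModel <- function(emp, modelName, init) {
  ## Cressie WLS weights N_j / gamma(h_j)^2: short lags dominate, which is
  ## where the range is identified
  obj <- function(par) {
    m <- list(model = modelName, nugget = par[1L], psill = par[2L],
              range = par[3L])
    g <- variogramValue(m, emp$dist)
    sum(emp$npairs / pmax(g, 1e-10)^2 * (emp$gamma - g)^2)
  }
  optim(init, obj, method = "L-BFGS-B",
        lower = c(0, 0, 1e-6 * max(emp$dist)),
        upper = c(Inf, Inf, 10 * max(emp$dist)))
}

#' Fit a variogram model to point data
#'
#' Computes the empirical semivariogram over equal-width distance bins
#' (default 12, maximum lag = half the maximum pairwise distance) and fits
#' a spherical model by weighted least squares with Cressie weights
#' (`npairs / gamma_model^2`, emphasizing the short lags that identify the
#' range), falling back to an exponential model when the spherical fit fails to
#' converge or fits worse. Degenerate inputs (all values identical) return
#' a pure-nugget model with zero sill, under which kriging returns a
#' constant surface.
#'
#' @param coords two-column matrix of planar coordinates (>= 30 points).
#' @param values numeric values at the points.
#' @param nBins number of equal-width distance bins.
#' @param model `"spherical"` (default) or `"exponential"`.
#' @param maxLagFrac maximum lag as a fraction of the maximum pairwise
#'   distance.
#' @return list of class `variogramModel`: `model`, `nugget`, `psill`,
#'   `sill` (= nugget + psill), `range`, `empirical` (binned data.frame),
#'   `converged`.
#' @export
fitVariogram <- function(coords, values, nBins = 12,
                         model = c("spherical", "exponential"),
                         maxLagFrac = 0.5) {
  model <- match.arg(model)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (nrow(coords) < 30)
    stop("need at least 30 points to fit a variogram", call. = FALSE)
  if (var(values) == 0) {
    out <- list(model = "nugget", nugget = 0, psill = 0, sill = 0,
                range = 0, empirical = NULL, converged = TRUE,
                degenerate = TRUE)
    class(out) <- "variogramModel"
    return(out)
  }
  emp <- empiricalVariogram(coords, values, nBins, maxLagFrac)
  s0 <- var(values)
  init <- c(nugget = max(min(emp$gamma) / 2, 1e-10 * s0),
            psill = max(s0 - min(emp$gamma) / 2, 0.1 * s0),
            range = stats::median(emp$dist))
  fitted <- tryCatch(fitVariogramModel(emp, model, init),
                     error = function(e) NULL)
  usedModel <- model
  if ((is.null(fitted) || fitted$convergence != 0) && model == "spherical") {
    alt <- tryCatch(fitVariogramModel(emp, "exponential", init),
                    error = function(e) NULL)
    if (!is.null(alt) && (is.null(fitted) || alt$value < fitted$value)) {
      fitted <- alt
      usedModel <- "exponential"
    }
  }
  if (is.null(fitted))
    stop("variogram fit failed for both spherical and exponential models",
         call. = FALSE)
  out <- list(model = usedModel, nugget = fitted$par[1L],
              psill = fitted$par[2L],
              sill = fitted$par[1L] + fitted$par[2L],
              range = fitted$par[3L], empirical = emp,
              converged = fitted$convergence == 0, degenerate = FALSE)
  class(out) <- "variogramModel"
  out
}

#' @export
print.variogramModel <- function(x, ...) {
  cat(sprintf("variogramModel: %s (nugget %.4g, partial sill %.4g, range %.4g)%s\n",
              x$model, x$nugget, x$psill, x$range,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Ordinary kriging interpolation
#'
#' Best linear unbiased interpolation with weights constrained to sum to 1
#' at every prediction location (the ordinary-kriging unbiasedness
#' constraint), solving the standard augmented linear system built from the
#' fitted semivariogram. With a zero nugget the interpolator is exact at
#' the data points. Uses all data points (global neighbourhood).
#'
#' @param coords,values data locations and values.
#' @param model a `variogramModel` from [fitVariogram()].
#' @param newCoords two-column matrix of prediction locations.
#' @param returnWeights also return the full weight matrix.
#' @return list: `predictions`, `weightSums` (all ~1), optionally `weights`
#'   (n x m matrix).
#' @export
krigeOrdinary <- function(coords, values, model, newCoords,
                          returnWeights = FALSE) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  newCoords <- as.matrix(newCoords)[, 1:2, drop = FALSE]
  n <- nrow(coords); m <- nrow(newCoords)
  if (model$model == "nugget" || model$sill <= 0) {
    return(list(predictions = rep(mean(values), m),
                weightSums = rep(1, m),
                weights = if (returnWeights)
                  matrix(1 / n, n, m) else NULL))
  }
  G <- variogramValue(model, as.matrix(dist(coords)))
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(rowSums(coords^2), rowSums(newCoords^2), `+`) -
               2 * coords %*% t(newCoords))
  d0[!is.finite(d0) | d0 < 0] <- 0
  rhs <- rbind(variogramValue(model, d0), 1)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8 * model$sill
    solve(A, rhs)
  })
  w <- sol[seq_len(n), , drop = FALSE]
  list(predictions = as.numeric(crossprod(w, values)),
       weightSums = colSums(w),
       weights = if (returnWeights) w else NULL)
}

#' Kriged, 0-1 scaled model-error surface
#'
#' The per-station model error `e_i = |observed_i - predicted_i|` is
#' interpolated over the unmasked grid cells by ordinary kriging with a
#' variogram fitted by [fitVariogram()], negative kriged values are clipped
#' to zero, and the surface is divided by the maximum observed absolute
#' error so 1 marks the largest prediction error (`scaleBasis`, stored).
#'
#' @param coords two-column matrix of station coordinates (>= 30).
#' @param observed,predicted aligned observation and prediction vectors.
#' @param env an [EnvironmentGrid-class] defining the prediction domain.
#' @param nBins,model passed to [fitVariogram()].
#' @return an [ErrorRaster-class].
#' @export
errorSurface <- function(coords, observed, predicted, env, nBins = 12,
                         model = "spherical") {
  stopifnot(is(env, "EnvironmentGrid"), length(observed) == length(predicted))
  e <- abs(observed - predicted)
  dims <- gridDim(env)
  keep <- as.vector(env@mask)
  vals <- rep(NA_real_, prod(dims))
  if (max(e) == 0) {
    vgm <- list(model = "nugget", nugget = 0, psill = 0, sill = 0,
                range = 0, degenerate = TRUE)
    class(vgm) <- "variogramModel"
    vals[keep] <- 0
    return(new("ErrorRaster", values = matrix(vals, dims[1L], dims[2L]),
               cellSize = env@cellSize, origin = env@origin,
               flagged = matrix(FALSE, dims[1L], dims[2L]),
               variogram = unclass(vgm), scaleBasis = 0))
  }
  vgm <- fitVariogram(coords, e, nBins = nBins, model = model)
  ctr <- cellCenters(dims, env@cellSize, env@origin)
  cellIdx <- which(keep)
  r <- ((cellIdx - 1L) %% dims[1L]) + 1L
  c <- ((cellIdx - 1L) %/% dims[1L]) + 1L
  kk <- krigeOrdinary(coords, e, vgm, cbind(ctr$x[c], ctr$y[r]))
  scaled <- pmin(pmax(kk$predictions, 0) / max(e), 1)
  vals[cellIdx] <- scaled
  new("ErrorRaster", values = matrix(vals, dims[1L], dims[2L]),
      cellSize = env@cellSize, origin = env@origin,
      flagged = matrix(FALSE, dims[1L], dims[2L]),
      variogram = unclass(vgm), scaleBasis = max(e))
}
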