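## Synthetic seascapes and depth-stratified random trawl surveys with the
## statistical structure the delta-model analysis assumes: smooth
## species-environment responses, zero inflation (Bernoulli occurrence) and
## overdispersion (zero-truncated negative-binomial positive counts).

## Gaussian random field on a grid by spectral (FFT) smoothing of white
## noise with a Gaussian kernel; unit variance, mean zero, deterministic
## given the RNG state.
gaussianRandomField <- function(nRows, nCols, rangeCells = 6) {
  w <- matrix(rnorm(nRows * nCols), nRows, nCols)
  ri <- c(0:(nRows %/% 2), -((nRows - nRows %/% 2 - 1):1))
  ci <- c(0:(nCols %/% 2), -((nCols - nCols %/% 2 - 1):1))
  d2 <- outer(ri^2, ci^2, `+`)
  kern <- exp(-d2 / (2 * rangeCells^2))
  f <- Re(fft(fft(w) * Re(fft(kern)), inverse = TRUE)) / (nRows * nCols)
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic seascape
#'
#' Builds an aligned five-layer environmental raster emulating a
#' continental-margin study area: a depth surface with a shallow coastal
#' band, a mid-depth bank (~100 m), a shelf and a deep basin (>= 800 m);
#' smooth sea-surface temperature and salinity gradients, each perturbed by
#' a Gaussian-random-field noise term; and slope/rugosity layers derived
#' from the depth surface via [computeSlope()] and [computeRugosity()].
#' Two calls with the same seed return identical grids.
#'
#' @param nRows,nCols grid dimensions (cells, >= 32 each).
#' @param cellSize cell side, metres (default 866, a 30 arc-second cell at
#'   mid-latitudes).
#' @param seed integer RNG seed.
#' @param noiseAmplitude named list of GRF noise standard deviations:
#'   `depth` (m), `sst` (deg C), `salinity` (PSU).
#' @param noiseRange GRF correlation range, cells.
#' @return an [EnvironmentGrid-class] with layers `depth`, `slope`,
#'   `rugosity`, `salinity`, `sst`.
#' @examples
#' env <- generateEnvironment(32, 32, seed = 1)
#' range(env[["depth"]])
#' @export
generateEnvironment <- function(nRows = 64, nCols = 64, cellSize = 866,
                                seed = 1,
                                noiseAmplitude = list(depth = 25,
                                                      sst = 0.9,
                                                      salinity = 0.12),
                                noiseRange = 5) {
  if (nRows < 32 || nCols < 32)
    stop("grid must be at least 32x32 cells", call. = FALSE)
  if (cellSize <= 0) stop("cellSize must be positive", call. = FALSE)
  set.seed(seed)
  u <- matrix(rep((seq_len(nCols) - 1) / (nCols - 1), each = nRows),
              nRows, nCols)
  v <- matrix(rep((seq_len(nRows) - 1) / (nRows - 1), nCols), nRows, nCols)
  ## offshore gradient: shallow coastal strip (NW) to deep basin (SE)
  g <- 0.55 * u + 0.45 * v
  depth <- 15 + 1150 * g^1.7
  ## shallow offshore bank (~100 m plateau)
  bank <- 95 + 3500 * ((u - 0.22)^2 + (v - 0.62)^2)
  depth <- pmin(depth, bank)
  depth <- depth + noiseAmplitude$depth * gaussianRandomField(nRows, nCols,
                                                              noiseRange)
  depth <- pmin(pmax(depth, 11), 1400)
  sst <- 17.8 + 2.4 * v +
    noiseAmplitude$sst * gaussianRandomField(nRows, nCols, 2 * noiseRange)
  salinity <- 37.95 + 0.22 * u +
    noiseAmplitude$salinity * gaussianRandomField(nRows, nCols,
                                                  2 * noiseRange)
  slope <- computeSlope(depth, cellSize)
  rugosity <- computeRugosity(depth, cellSize)
  newEnvironmentGrid(
    layers = list(depth = depth, slope = slope@values,
                  rugosity = rugosity@values, salinity = salinity,
                  sst = sst),
    cellSize = cellSize)
}

## ---- species truth ----------------------------------------------------------

shapeFunction <- function(spec) {
  type <- spec$type
  if (is.null(type)) stop("shape spec needs a 'type'", call. = FALSE)
  switch(type,
    logistic = {
      mid <- spec$midpoint; rate <- spec$rate
      function(x) stats::plogis(rate * (x - mid))
    },
    gaussian = {
      ctr <- spec$center; wd <- spec$width
      function(x) exp(-(x - ctr)^2 / (2 * wd^2))
    },
    constant = function(x) rep(1, length(x)),
    stop("unknown response shape '", type,
         "'; use logistic, gaussian or constant", call. = FALSE))
}

#' Define a synthetic species-environment truth
#'
#' Constructs a known occurrence probability surface `p` and positive mean
#' density surface `mu` as products of univariate response shapes over the
#' named predictors, scaled by `pMax` and `muMax`. Shapes: `logistic`
#' (`midpoint`, `rate`; negative rate = decreasing), `gaussian` (`center`,
#' `width`), `constant`. Predictors without a shape have exactly zero
#' effect, which `activePredictors` documents for subset-recovery tests.
#'
#' @param speciesId character identifier.
#' @param occurrenceShapes named list (by predictor) of shape specs for `p`.
#' @param abundanceShapes named list of shape specs for `mu`; defaults to
#'   `occurrenceShapes`.
#' @param pMax maximum occurrence probability, in (0, 1].
#' @param muMax maximum mean density, N km^-2.
#' @param dispersion negative-binomial size parameter k > 0 (smaller =
#'   more overdispersed).
#' @return a [SpeciesTruth-class].
#' @examples
#' tr <- defineSpeciesTruth("ray_like",
#'   occurrenceShapes = list(depth = list(type = "logistic",
#'                                        midpoint = 450, rate = -0.012)))
#' tr@occurrence(data.frame(depth = c(100, 700)))
#' @export
defineSpeciesTruth <- function(speciesId, occurrenceShapes = list(),
                               abundanceShapes = occurrenceShapes,
                               pMax = 0.9, muMax = 50, dispersion = 1) {
  stopifnot(pMax > 0, pMax <= 1, muMax > 0)
  bad <- setdiff(union(names(occurrenceShapes), names(abundanceShapes)),
                 predictorNames())
  if (length(bad))
    stop("shapes reference unknown predictors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  occF <- lapply(occurrenceShapes, shapeFunction)
  abuF <- lapply(abundanceShapes, shapeFunction)
  productResponse <- function(funs, scale) {
    force(funs); force(scale)
    function(data) {
      out <- rep(scale, nrow(data))
      for (nm in names(funs)) out <- out * funs[[nm]](data[[nm]])
      out
    }
  }
  active <- as.character(union(names(occurrenceShapes),
                               names(abundanceShapes)))
  new("SpeciesTruth", speciesId = speciesId,
      occurrence = productResponse(occF, pMax),
      abundance = productResponse(abuF, muMax),
      dispersion = dispersion, activePredictors = active,
      shapes = list(occurrence = occurrenceShapes,
                    abundance = abundanceShapes))
}

## ---- survey design & simulation --------------------------------------------

#' Depth-stratified survey design
#'
#' @param strata two-column matrix of stratum depth bounds (m); default the
#'   five standard trawl-survey strata 10-50, 50-100, 100-200, 200-500,
#'   500-800 m (first stratum closed, the rest half-open `(lower, upper]`).
#' @param nStations stations per survey year, allocated proportionally to
#'   stratum area with largest-remainder rounding.
#' @param sweptArea swept area per haul, km^2.
#' @return a [SurveyDesign-class].
#' @export
surveyDesign <- function(strata = defaultStrata(), nStations = 120,
                         sweptArea = 0.06) {
  new("SurveyDesign", strata = strata, nStations = as.integer(nStations),
      sweptArea = sweptArea)
}

#' @rdname surveyDesign
#' @export
defaultStrata <- function() {
  m <- matrix(c(10, 50, 50, 100, 100, 200, 200, 500, 500, 800),
              ncol = 2L, byrow = TRUE)
  dimnames(m) <- list(NULL, c("lower", "upper"))
  m
}

## stratum membership: first interval closed, others half-open (lower, upper]
assignStratum <- function(depth, strata) {
  out <- rep(NA_integer_, length(depth))
  for (s in seq_len(nrow(strata))) {
    lo <- strata[s, 1L]; hi <- strata[s, 2L]
    inS <- if (s == 1L) depth >= lo & depth <= hi else depth > lo & depth <= hi
    out[!is.na(depth) & inS & is.na(out)] <- s
  }
  out
}

#' Largest-remainder proportional allocation
#'
#' Allocates `n` stations to strata proportionally to `areas`, rounding by
#' the largest-remainder rule (floors first, remaining stations to the
#' largest fractional parts, ties to the earlier stratum).
#'
#' @param areas positive stratum areas (any common unit).
#' @param n total stations.
#' @return integer allocation summing to `n`.
#' @export
allocateStations <- function(areas, n) {
  q <- n * areas / sum(areas)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

## zero-truncated negative binomial sampler (inverse-CDF above P(0))
rztnbinom <- function(n, mu, size) {
  if (n == 0L) return(integer())
  p0 <- pnbinom(0, size = size, mu = mu)
  u <- runif(n, min = p0, max = 1)
  pmax(qnbinom(u, size = size, mu = mu), 1L)
}

#' Simulate a stratified random trawl survey
#'
#' Places stations uniformly at random within each depth stratum's eligible
#' cells (allocation proportional to stratum area, largest-remainder
#' rounding), samples the five predictors at station cells, and draws
#' per-species catches from a hurdle data-generating process: presence ~
#' Bernoulli(p(x)); conditional on presence, count ~ zero-truncated
#' negative binomial with mean `mu(x) * sweptArea` and size `k`; density =
#' count / sweptArea (N km^-2). Station coordinates are jittered within the
#' cell. `year` is a replication index only (stations are redrawn each
#' year); it enters no model term.
#'
#' @param env an [EnvironmentGrid-class].
#' @param truths list of [SpeciesTruth-class] objects.
#' @param design a [SurveyDesign-class].
#' @param nYears survey years (total rows = `nYears * nStations`).
#' @param seed integer RNG seed.
#' @return a survey table (`data.frame`): `station_id`, `x`, `y`, `year`,
#'   `stratum`, the five predictors, `density_<id>`, `presence_<id>` per
#'   species, and `richness` (count of species with positive density).
#' @export
simulateSurvey <- function(env, truths, design = surveyDesign(), nYears = 1,
                           seed = 1) {
  stopifnot(is(env, "EnvironmentGrid"), is(design, "SurveyDesign"))
  if (is(truths, "SpeciesTruth")) truths <- list(truths)
  set.seed(seed)
  depth <- gridLayer(env, "depth")
  strat <- assignStratum(as.vector(depth), design@strata)
  cells <- lapply(seq_len(nrow(design@strata)), function(s)
    which(strat == s & as.vector(env@mask)))
  nCells <- vapply(cells, length, integer(1))
  if (any(nCells == 0L))
    stop("stratum with no eligible cells: ",
         paste(sprintf("[%g, %g] m", design@strata[nCells == 0L, 1L],
                       design@strata[nCells == 0L, 2L]), collapse = ", "),
         call. = FALSE)
  alloc <- allocateStations(nCells, design@nStations)
  dims <- gridDim(env)
  ctr <- cellCenters(dims, env@cellSize, env@origin)
  rows <- vector("list", nYears)
  for (yr in seq_len(nYears)) {
    cellIdx <- unlist(lapply(seq_along(cells), function(s)
      cells[[s]][sample.int(nCells[s], alloc[s],
                            replace = alloc[s] > nCells[s])]))
    r <- ((cellIdx - 1L) %% dims[1L]) + 1L
    c <- ((cellIdx - 1L) %/% dims[1L]) + 1L
    x <- ctr$x[c] + runif(length(c), -0.49, 0.49) * env@cellSize
    y <- ctr$y[r] + runif(length(r), -0.49, 0.49) * env@cellSize
    pred <- data.frame(lapply(names(env@layers), function(nm)
      env@layers[[nm]][cbind(r, c)]))
    names(pred) <- names(env@layers)
    tab <- data.frame(station_id = NA_character_, x = x, y = y, year = yr,
                      stratum = assignStratum(pred$depth, design@strata),
                      pred, stringsAsFactors = FALSE)
    ## stratum of record = stratum the station was drawn in
    tab$stratum <- rep(seq_along(alloc), alloc)
    for (tr in truths) {
      p <- pmin(pmax(tr@occurrence(pred), 0), 1)
      mu <- tr@abundance(pred)
      if (any(mu <= 0)) stop("abundance truth must be positive everywhere",
                             call. = FALSE)
      pres <- rbinom(nrow(pred), 1L, p)
      count <- integer(nrow(pred))
      idx <- which(pres == 1L)
      count[idx] <- rztnbinom(length(idx), mu[idx] * design@sweptArea,
                              tr@dispersion)
      tab[[paste0("density_", tr@speciesId)]] <- count / design@sweptArea
      tab[[paste0("presence_", tr@speciesId)]] <- as.integer(count > 0)
    }
    rows[[yr]] <- tab
  }
  out <- do.call(rbind, rows)
  out$station_id <- sprintf("Y%02d_S%03d", out$year,
                            unlist(lapply(rows, function(t) seq_len(nrow(t)))))
  rownames(out) <- NULL
  computeRichness(out)
}

#' Per-station species richness
#'
#' Appends (or recomputes) `richness`: the number of species with positive
#' density in each haul, i.e. the actual number of species in the sample.
#'
#' @param survey a survey table with `density_*` columns.
#' @return the survey table with a `richness` integer column.
#' @export
computeRichness <- function(survey) {
  dens <- grep("^density_", names(survey), value = TRUE)
  if (!length(dens)) {
    survey$richness <- 0L
    return(survey)
  }
  survey$richness <- as.integer(
    rowSums(as.matrix(survey[, dens, drop = FALSE]) > 0))
  survey
}

#' A default assemblage of synthetic species truths
#'
#' Six species spanning the response patterns a demersal trawl survey
#' typically shows: a shallow-water species with a decreasing logistic depth
#' response (inflexion near 450 m), a deep-water species, a mid-depth
#' specialist with a unimodal (Gaussian) depth optimum near 600 m,
#' a thermophilic shallow species with an SST response, a rugosity-affine
#' species, and a rare species (low `pMax`) expected to fail the 5%
#' occurrence filter at moderate survey sizes.
#'
#' @return named list of [SpeciesTruth-class] objects.
#' @export
defaultSpeciesTruths <- function() {
  list(
    shallow_ray = defineSpeciesTruth("shallow_ray",
      occurrenceShapes = list(depth = list(type = "logistic", midpoint = 450,
                                           rate = -0.012)),
      abundanceShapes = list(depth = list(type = "logistic", midpoint = 400,
                                          rate = -0.008)),
      pMax = 0.85, muMax = 60, dispersion = 0.8),
    deep_shark = defineSpeciesTruth("deep_shark",
      occurrenceShapes = list(depth = list(type = "logistic", midpoint = 500,
                                           rate = 0.012),
                              sst = list(type = "gaussian", center = 20,
                                         width = 2.5)),
      pMax = 0.8, muMax = 35, dispersion = 1),
    mid_chimaera = defineSpeciesTruth("mid_chimaera",
      occurrenceShapes = list(depth = list(type = "gaussian", center = 600,
                                           width = 180)),
      pMax = 0.75, muMax = 40, dispersion = 1.2),
    warm_torpedo = defineSpeciesTruth("warm_torpedo",
      occurrenceShapes = list(depth = list(type = "logistic", midpoint = 250,
                                           rate = -0.02),
                              sst = list(type = "logistic", midpoint = 19.5,
                                         rate = 1.2)),
      pMax = 0.6, muMax = 25, dispersion = 0.7),
    rough_dogfish = defineSpeciesTruth("rough_dogfish",
      occurrenceShapes = list(depth = list(type = "gaussian", center = 300,
                                           width = 250),
                              rugosity = list(type = "logistic",
                                              midpoint = 2e-6,
                                              rate = 8e5)),
      pMax = 0.55, muMax = 30, dispersion = 1),
    rare_skate = defineSpeciesTruth("rare_skate",
      occurrenceShapes = list(depth = list(type = "gaussian", center = 200,
                                           width = 150)),
      pMax = 0.04, muMax = 10, dispersion = 1)
  )
}
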