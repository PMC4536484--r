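toyVariogram <- function(nugget = 0, psill = 2, range = 50,
                         model = "spherical") {
  structure(list(model = model, nugget = nugget, psill = psill,
                 sill = nugget + psill, range = range, degenerate = FALSE),
            class = "variogramModel")
}

test_that("empirical semivariance bins match a brute-force computation", {
  set.seed(15)
  coords <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  vals <- rnorm(60)
  emp <- deltahab:::empiricalVariogram(coords, vals, nBins = 8,
                                       maxLagFrac = 0.5)
  D <- as.matrix(dist(coords))
  maxLag <- 0.5 * max(D)
  brute <- data.frame(dist = numeric(), gamma = numeric())
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pairs]; g <- 0.5 * (vals[pairs[, 1]] - vals[pairs[, 2]])^2
  keep <- d <= maxLag & d > 0
  d <- d[keep]; g <- g[keep]
  brk <- seq(0, max(d), length.out = 9)
  cl <- findInterval(d, brk, rightmost.closed = TRUE, all.inside = TRUE)
  bins <- sort(unique(cl))
  expect_identical(nrow(emp), length(bins))
  for (i in seq_along(bins)) {
    b <- bins[i]
    expect_equal(emp$dist[i], mean(d[cl == b]), tolerance = 1e-9)
    expect_equal(emp$gamma[i], mean(g[cl == b]), tolerance = 1e-9)
    expect_equal(emp$npairs[i], sum(cl == b))
  }
})

test_that("variogram fitting recovers a known spherical model", {
  sills <- ranges <- numeric(10)
  for (sd in 1:10) {
    set.seed(sd)
    coords <- cbind(runif(400, 0, 100), runif(400, 0, 100))
    z <- sphericalFieldFactory(coords, range = 30)()
    v <- fitVariogram(coords, z)
    sills[sd] <- v$sill; ranges[sd] <- v$range
    expect_gte(v$nugget, 0)
    expect_gte(v$psill, 0)
    expect_gte(v$range, 0)
  }
  expect_lt(abs(median(sills) - 1), 0.25)
  expect_lt(abs(median(ranges) - 30) / 30, 0.25)
})

test_that("constant values give a degenerate pure-nugget variogram and constant kriging", {
  set.seed(16)
  coords <- cbind(runif(40), runif(40))
  v <- fitVariogram(coords, rep(3.3, 40))
  expect_identical(v$model, "nugget")
  expect_equal(v$sill, 0)
  kk <- krigeOrdinary(coords, rep(3.3, 40), v, cbind(0.5, 0.5))
  expect_equal(kk$predictions, 3.3)
  expect_error(fitVariogram(coords[1:10, ], rnorm(10)), "at least 30")
})

test_that("ordinary kriging matches a direct solve of the 3-point system", {
  vg <- toyVariogram()
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10))
  vals <- c(1, 3, 2)
  target <- rbind(c(5, 5), c(2, 8))
  kk <- krigeOrdinary(pts, vals, vg, target, returnWeights = TRUE)
  gam0 <- function(h) ifelse(h <= 0, 0,
    ifelse(h < 50, 2 * (1.5 * h / 50 - 0.5 * (h / 50)^3), 2))
  D <- as.matrix(dist(pts))
  A <- rbind(cbind(gam0(D), 1), c(1, 1, 1, 0))
  for (j in 1:2) {
    h0 <- sqrt(rowSums((pts - matrix(target[j, ], 3, 2, byrow = TRUE))^2))
    w <- solve(A, c(gam0(h0), 1))
    expect_equal(kk$predictions[j], sum(w[1:3] * vals), tolerance = 1e-9)
  }
  expect_equal(kk$weightSums, c(1, 1), tolerance = 1e-12)
})

test_that("zero-nugget kriging is exact at the data points with unit weight sums", {
  set.seed(17)
  coords <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  vals <- rnorm(40)
  vg <- toyVariogram(nugget = 0, psill = 1.5, range = 40)
  kk <- krigeOrdinary(coords, vals, vg, coords, returnWeights = TRUE)
  expect_equal(kk$predictions, vals, tolerance = 1e-6)
  expect_equal(kk$weightSums, rep(1, 40), tolerance = 1e-9)
  # weight sums are 1 at arbitrary prediction locations too
  kk2 <- krigeOrdinary(coords, vals, vg, cbind(runif(25, 0, 100),
                                               runif(25, 0, 100)))
  expect_equal(kk2$weightSums, rep(1, 25), tolerance = 1e-9)
})

test_that("prediction rasters agree with tabular predictions at station cells", {
  env <- generateEnvironment(32, 32, 866, seed = 18)
  sv <- simulateSurvey(env, truthDepthSst(), surveyDesign(nStations = 150),
                       nYears = 2, seed = 19)
  fit <- fitHurdle(sv, "density_recov", c("depth", "sst"))
  ras <- predictRaster(fit, env)
  atStations <- sampleAtPoints(
    new("PredictionRaster", values = layerValues(ras),
        cellSize = env@cellSize, origin = env@origin,
        flagged = ras@flagged, mode = "delta",
        extrapolated = ras@extrapolated),
    sv[, c("x", "y")])
  tabular <- as.numeric(predictDelta(fit, sv))
  expect_equal(atStations, tabular, tolerance = 1e-9)
  # intercept-only fit gives a constant raster
  fit0 <- fitComponent(sv, "density_recov", "occurrence", character())
  ras0 <- predictRaster(fit0, env)
  expect_equal(length(unique(round(as.vector(layerValues(ras0)), 12))), 1L)
  # delta raster = occurrence x positive rasters elementwise
  ro <- predictRaster(fit@occurrence, env)
  rp <- predictRaster(fit@positive, env)
  expect_equal(layerValues(ras), layerValues(ro) * layerValues(rp),
               tolerance = 1e-12)
})

test_that("error surfaces are kriged, clipped and scaled to [0, 1]", {
  env <- generateEnvironment(32, 32, 866, seed = 20)
  set.seed(21)
  n <- 60
  dims <- gridDim(env)
  coords <- cbind(runif(n, 0, (dims[2] - 1) * 866),
                  runif(n, -(dims[1] - 1) * 866, 0))
  obs <- runif(n, 0, 50)
  pred <- obs + rnorm(n, sd = 5)
  er <- errorSurface(coords, obs, pred, env)
  vals <- layerValues(er)
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  expect_equal(er@scaleBasis, max(abs(obs - pred)))
  expect_true(er@variogram$model %in% c("spherical", "exponential"))
  # exact predictions give the flat zero raster
  er0 <- errorSurface(coords, obs, obs, env)
  expect_true(all(layerValues(er0) == 0, na.rm = TRUE))
  expect_equal(er0@scaleBasis, 0)
})

test_that("masked cells stay missing in prediction and error rasters", {
  env <- generateEnvironment(32, 32, 866, seed = 22)
  env@mask[1:5, 1:5] <- FALSE
  sv <- simulateSurvey(env, truthDepthSst(), surveyDesign(nStations = 100),
                       nYears = 1, seed = 23)
  fit <- fitHurdle(sv, "density_recov", "depth")
  ras <- predictRaster(fit, env)
  expect_true(all(is.na(layerValues(ras)[1:5, 1:5])))
  expect_true(all(!is.na(layerValues(ras)[10:20, 10:20])))
})
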