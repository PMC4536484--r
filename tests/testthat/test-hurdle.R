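makeToySurvey <- function(n = 400, seed = 1) {
  set.seed(seed)
  depth <- runif(n, 20, 800)
  sst <- runif(n, 17, 21)
  p <- plogis(-0.012 * (depth - 450))
  mu <- 30 * plogis(-0.008 * (depth - 400))
  pres <- rbinom(n, 1, p)
  count <- ifelse(pres == 1, deltahab:::rztnbinom(n, mu * 0.06, 1), 0)
  data.frame(depth = depth, sst = sst, slope = runif(n, 0, 5),
             rugosity = runif(n, 0, 1e-4), salinity = runif(n, 37.9, 38.3),
             density_toy = count / 0.06)
}

test_that("intercept-only occurrence fit matches the sample presence rate", {
  sv <- makeToySurvey(600, seed = 2)
  frac <- mean(sv$density_toy > 0)
  fit <- fitComponent(sv, "density_toy", "occurrence", character())
  pr <- predictComponent(fit, sv)
  expect_true(all(abs(pr - frac) < 0.01))
  expect_equal(length(unique(round(pr, 12))), 1L)  # all equal
})

test_that("occurrence predictions are probabilities and positive part sees no zeros", {
  sv <- makeToySurvey(400, seed = 3)
  occ <- fitComponent(sv, "density_toy", "occurrence", c("depth", "sst"))
  pr <- predictComponent(occ, sv)
  expect_true(all(pr >= 0 & pr <= 1))
  pos <- fitComponent(sv, "density_toy", "positive", "depth")
  expect_identical(pos@n, sum(sv$density_toy > 0))
  expect_gt(min(predictComponent(pos, sv)), 0)
})

test_that("degenerate and insufficient responses raise contract errors", {
  sv <- makeToySurvey(100, seed = 4)
  sv$allzero <- 0
  expect_error(fitComponent(sv, "allzero", "occurrence"), "degenerate")
  sv$allone <- 1
  expect_error(fitComponent(sv, "allone", "occurrence"), "degenerate")
  few <- sv[sv$density_toy > 0, ][1:12, ]
  expect_error(fitComponent(few, "density_toy", "positive",
                            c("depth", "sst")), "insufficient")
  expect_error(fitComponent(sv, "density_toy", "occurrence", "nope"),
               "missing predictor")
})

test_that("positive part on constant density explains no deviance", {
  sv <- makeToySurvey(300, seed = 5)
  sv$density_const <- ifelse(sv$density_toy > 0, 50, 0)
  fit <- fitComponent(sv, "density_const", "positive", "depth")
  expect_lt(fit@devianceExplained, 1e-6)
})

test_that("delta prediction is the product of the parts, zero where p is zero", {
  sv <- makeToySurvey(500, seed = 6)
  fit <- fitHurdle(sv, "density_toy", c("depth", "sst"), "depth")
  p <- predictComponent(fit@occurrence, sv)
  m <- predictComponent(fit@positive, sv)
  d <- predictDelta(fit, sv)
  expect_equal(as.numeric(d), as.numeric(p) * as.numeric(m),
               tolerance = 1e-12)
  expect_true(all(d >= 0))
  bin <- fitHurdle(sv, "density_toy", "depth", mode = "binomial_only")
  expect_error(predictDelta(bin, sv), "binomial_only")
})

test_that("grid prediction equals row-wise prediction of the flattened grid", {
  env <- generateEnvironment(32, 32, 866, seed = 7)
  sv <- simulateSurvey(env, truthDepthSst(), surveyDesign(nStations = 120),
                       nYears = 3, seed = 8)
  fit <- fitHurdle(sv, "density_recov", c("depth", "sst"))
  ras <- predictRaster(fit, env)
  cells <- as.data.frame(lapply(env@layers, as.vector))
  rowwise <- as.numeric(predictDelta(fit, cells))
  expect_equal(as.vector(layerValues(ras)), rowwise, tolerance = 1e-12)
  # occurrence-part raster obeys the probability range
  occRas <- predictRaster(fit@occurrence, env)
  expect_true(all(layerValues(occRas) >= 0 & layerValues(occRas) <= 1))
})

test_that("extrapolation beyond the training range is flagged per row", {
  sv <- makeToySurvey(300, seed = 9)
  fit <- fitComponent(sv, "density_toy", "occurrence", "depth")
  nd <- data.frame(depth = c(mean(sv$depth), max(sv$depth) + 100))
  pr <- predictComponent(fit, nd)
  expect_identical(attr(pr, "extrapolated"), c(FALSE, TRUE))
})

test_that("fitted depth effect is monotone when the truth is a pure logistic", {
  monotone <- vapply(1:5, function(sd) {
    sv <- makeToySurvey(900, seed = 20 + sd)
    fit <- fitComponent(sv, "density_toy", "occurrence", "depth")
    eff <- smoothEffect(fit, "depth", n = 100)
    all(diff(eff$effect) <= 1e-8)
  }, logical(1))
  expect_gte(sum(monotone), 4)
})

test_that("adding a term never decreases the log-likelihood at fixed smoothing", {
  sv <- makeToySurvey(400, seed = 30)
  sv$.y <- as.numeric(sv$density_toy > 0)
  f0 <- mgcv::gam(.y ~ 1, family = binomial(), data = sv)
  for (sp in c(0.1, 10, 1000)) {
    f1 <- mgcv::gam(.y ~ s(depth, k = 5, bs = "cs") +
                      s(sst, k = 5, bs = "cs"),
                    family = binomial(), data = sv, sp = c(sp, sp))
    expect_gte(as.numeric(logLik(f1)) - as.numeric(logLik(f0)), -1e-6)
  }
})

test_that("smooth effects come with pointwise 95% bands", {
  sv <- makeToySurvey(400, seed = 31)
  fit <- fitComponent(sv, "density_toy", "occurrence", c("depth", "sst"))
  eff <- smoothEffect(fit, "depth")
  expect_true(all(eff$lower <= eff$effect & eff$effect <= eff$upper))
  expect_error(smoothEffect(fit, "slope"), "not in fit")
})
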