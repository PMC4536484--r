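test_that("environment generation is seed-deterministic with valid layer ranges", {
  e1 <- generateEnvironment(64, 64, 866, seed = 1)
  e2 <- generateEnvironment(64, 64, 866, seed = 1)
  expect_identical(e1@layers, e2@layers)
  e3 <- generateEnvironment(64, 64, 866, seed = 2)
  expect_false(identical(e1@layers, e3@layers))

  sl <- e1[["slope"]]; rg <- e1[["rugosity"]]
  expect_true(all(sl >= 0 & sl <= 90))
  expect_true(all(rg >= 0 & rg <= 1))
  # depth surface spans the shallow bank / shelf / deep basin structure
  dp <- e1[["depth"]]
  expect_lt(min(dp), 50)
  expect_gt(max(dp), 800)
  expect_error(generateEnvironment(10, 10), "32x32")
})

test_that("generated predictor layers pass the collinearity screen at defaults", {
  env <- generateEnvironment(64, 64, 866, seed = 1)
  set.seed(1)
  idx <- sample(64 * 64, 500)
  cells <- as.data.frame(lapply(env@layers, function(m) as.vector(m)[idx]))
  v <- vifScreen(cells)
  expect_true(all(v$table$vif < 2))
})

test_that("species truth responses follow their stated shapes", {
  tr <- defineSpeciesTruth("ray",
    occurrenceShapes = list(depth = list(type = "logistic", midpoint = 450,
                                         rate = -0.012)))
  p <- tr@occurrence(data.frame(depth = c(400, 500)))
  expect_gt(p[1], p[2])                      # decreasing logistic
  expect_identical(tr@activePredictors, "depth")

  # Gaussian bump: argmax on a dense transect within one cell of the centre
  bump <- defineSpeciesTruth("chim",
    occurrenceShapes = list(depth = list(type = "gaussian", center = 600,
                                         width = 150)))
  dgrid <- seq(0, 800, by = 1)
  pk <- dgrid[which.max(bump@occurrence(data.frame(depth = dgrid)))]
  expect_lt(abs(pk - 600), 1 + 1e-9)

  # no active predictors: responses constant over the grid
  flatT <- defineSpeciesTruth("flat", pMax = 0.4, muMax = 10)
  vals <- flatT@occurrence(data.frame(depth = runif(50, 0, 800)))
  expect_equal(vals, rep(0.4, 50))
  expect_error(defineSpeciesTruth("bad",
    occurrenceShapes = list(depth = list(type = "wiggle"))), "unknown")
  expect_error(defineSpeciesTruth("bad2",
    occurrenceShapes = list(altitude = list(type = "constant"))),
    "unknown predictors")
})

test_that("station allocation follows the largest-remainder proportional rule", {
  expect_identical(allocateStations(c(1, 1, 2), 40), c(10L, 10L, 20L))
  expect_identical(allocateStations(c(1, 1, 1), 10), c(4L, 3L, 3L))
  set.seed(4)
  for (i in 1:20) {
    a <- runif(5, 1, 100); n <- sample(30:300, 1)
    alloc <- allocateStations(a, n)
    expect_equal(sum(alloc), n)
    expect_true(all(abs(alloc - n * a / sum(a)) < 1))
  }
})

test_that("survey simulation is stratified, deterministic and hurdle-consistent", {
  env <- generateEnvironment(48, 48, 866, seed = 3)
  des <- surveyDesign(nStations = 80)
  sv1 <- simulateSurvey(env, defaultSpeciesTruths()[1:2], des, nYears = 2,
                        seed = 9)
  sv2 <- simulateSurvey(env, defaultSpeciesTruths()[1:2], des, nYears = 2,
                        seed = 9)
  expect_identical(sv1, sv2)

  # every station's depth lies inside its recorded stratum
  strata <- defaultStrata()
  lo <- strata[sv1$stratum, 1]; hi <- strata[sv1$stratum, 2]
  expect_true(all(sv1$depth >= lo - 1e-9 & sv1$depth <= hi + 1e-9))

  # presence = 1 <=> density > 0, and density x swept area is integer
  for (sp in c("shallow_ray", "deep_shark")) {
    d <- sv1[[paste0("density_", sp)]]
    expect_identical(sv1[[paste0("presence_", sp)]], as.integer(d > 0))
    expect_true(all(abs(d * 0.06 - round(d * 0.06)) < 1e-9))
  }

  # allocation matches the proportional rule on stratum cell areas
  depth <- env[["depth"]]
  cellStrat <- deltahab:::assignStratum(as.vector(depth), strata)
  areas <- tabulate(cellStrat, nbins = 5)
  expect_identical(as.integer(table(sv1$stratum[sv1$year == 1])),
                   allocateStations(areas, 80))
})

test_that("empty strata are reported by name", {
  env <- generateEnvironment(48, 48, 866, seed = 3)
  shallowOnly <- matrix(30, 48, 48)
  env2 <- env
  env2@layers$depth <- shallowOnly
  expect_error(simulateSurvey(env2, defaultSpeciesTruths()[1],
                              surveyDesign(nStations = 40), seed = 1),
               "\\[50, 100\\]")
})

test_that("a null truth yields all-zero densities and richness contributions", {
  env <- generateEnvironment(32, 32, 866, seed = 2)
  zero <- defineSpeciesTruth("none", pMax = 1e-12, muMax = 5)
  sv <- simulateSurvey(env, zero, surveyDesign(nStations = 60), seed = 5)
  expect_true(all(sv$density_none == 0))
  expect_true(all(sv$richness == 0))
})

test_that("constant occurrence probability is recovered in frequency", {
  env <- generateEnvironment(48, 48, 866, seed = 6)
  tr <- truthNoise(p = 0.3)
  sv <- simulateSurvey(env, tr, surveyDesign(nStations = 200), nYears = 10,
                       seed = 11)
  phat <- mean(sv$density_noise > 0)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.3) / 2000
  expect_gte(phat, ci[1])
  expect_lte(phat, ci[2])
})

test_that("richness counts species with positive density per row", {
  toy <- data.frame(density_a = c(0, 3.2, 0), density_b = c(0, 11, 2),
                    density_c = c(0, 0, 1), density_d = c(0, 1, 0))
  out <- computeRichness(toy)
  expect_identical(out$richness, c(0L, 3L, 2L))

  set.seed(8)
  big <- as.data.frame(matrix(rbinom(37 * 50, 1, 0.2) * runif(37 * 50),
                              50, 37))
  names(big) <- paste0("density_sp", 1:37)
  out <- computeRichness(big)
  oracle <- apply(big > 0, 1, sum)
  expect_identical(out$richness, as.integer(oracle))
})

test_that("lowering occurrence uniformly increases the zero fraction", {
  env <- generateEnvironment(32, 32, 866, seed = 4)
  frac <- function(p, seed) {
    tr <- truthNoise(p = p)
    sv <- simulateSurvey(env, tr, surveyDesign(nStations = 100), seed = seed)
    mean(sv$density_noise == 0)
  }
  diffs <- vapply(1:20, function(s) frac(0.2, s) - frac(0.6, s), numeric(1))
  expect_gt(mean(diffs), 0)
  expect_true(all(diffs > 0))
})

test_that("positive counts are overdispersed, matching the NB variance", {
  # constant mu and k: sample variance of positive counts exceeds Poisson
  # and sits inside the Monte-Carlo band of the NB variance mu + mu^2/k
  mu <- 12; k <- 0.8
  set.seed(21)
  vars <- replicate(60, {
    x <- deltahab:::rztnbinom(400, mu = mu, size = k)
    var(x)
  })
  obs <- median(vars)
  expect_gt(obs, mu)  # exceeds the Poisson variance
  # reference band from the same zero-truncated sampler at large n
  ref <- replicate(200, var(deltahab:::rztnbinom(400, mu = mu, size = k)))
  expect_gte(obs, quantile(ref, 0.025))
  expect_lte(obs, quantile(ref, 0.975))
  # and the untruncated NB variance is the right order of magnitude
  expect_lt(abs(mean(vars) - (mu + mu^2 / k)) / (mu + mu^2 / k), 0.5)
})
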