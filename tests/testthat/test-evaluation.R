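test_that("train/test split is disjoint, exhaustive and reproducible", {
  fix <- recoverySurvey(seed = 5)
  sv <- fix$survey
  sp <- suppressWarnings(splitTrainTest(sv, ratio = 2 / 3, seed = 1))
  expect_identical(nrow(sp$train), 600L)
  expect_identical(nrow(sp$test), 300L)
  expect_identical(sort(c(sp$train$station_id, sp$test$station_id)),
                   sort(sv$station_id))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  sp2 <- suppressWarnings(splitTrainTest(sv, ratio = 2 / 3, seed = 1))
  expect_identical(sp$trainIdx, sp2$trainIdx)
  expect_error(splitTrainTest(sv[1:10, ]), "at least 30")
})

test_that("coverage report flags test ranges outside the training range", {
  fix <- recoverySurvey(seed = 6)
  sp <- suppressWarnings(splitTrainTest(fix$survey, seed = 2))
  expect_s3_class(sp, "trainTestSplit")
  expect_true(all(c("column", "covered") %in% names(sp$coverage)))
  for (cl in sp$coverage$column[sp$coverage$covered]) {
    expect_gte(min(sp$test[[cl]]), min(sp$train[[cl]]))
    expect_lte(max(sp$test[[cl]]), max(sp$train[[cl]]))
  }
})

test_that("corrected correlation is exact on rank-identical data", {
  set.seed(7)
  coords <- cbind(runif(50), runif(50))
  x <- rnorm(50)
  r <- correctedCorrelation(x, 2 * x + 5, coords)
  expect_equal(r$rS, 1)
  expect_equal(r$pValue, 0)
  expect_error(correctedCorrelation(rep(1, 50), x, coords), "constant")
  expect_error(correctedCorrelation(x[1:5], x[1:5], coords[1:5, ]),
               "at least 10")
})

test_that("white-noise fields need almost no effective-sample-size correction", {
  set.seed(8)
  coords <- cbind(runif(200), runif(200))
  neff <- vapply(1:20, function(s) {
    set.seed(100 + s)
    correctedCorrelation(rnorm(200), rnorm(200), coords)$nEff
  }, numeric(1))
  expect_lt(abs(median(neff) - 200) / 200, 0.1)
})

test_that("autocorrelated fields shrink n_eff and inflate the p-value", {
  set.seed(9)
  coords <- cbind(runif(150), runif(150))
  fieldGen <- sphericalFieldFactory(coords, range = 1 / 3)
  res <- replicate(25, {
    r <- correctedCorrelation(fieldGen(), fieldGen(), coords)
    c(r$nEff, r$pValue >= r$pValueUncorrected - 1e-12)
  })
  expect_lt(median(res[1, ]), 75)           # n_eff < n/2
  expect_true(all(res[2, ] == 1))           # corrected p never smaller
})

test_that("duplicate coordinates are jittered with a warning", {
  set.seed(10)
  coords <- cbind(c(runif(30), 0.5, 0.5), c(runif(30), 0.5, 0.5))
  expect_warning(correctedCorrelation(rnorm(32), rnorm(32), coords),
                 "jittered")
})

test_that("AUC matches brute-force pairwise concordance with tie half-credit", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(8:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))       # both classes present
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(rocAuc(labels, scores)$auc, aucOracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone from (0,0) to (1,1) and AUC classes follow bounds", {
  set.seed(12)
  labels <- rbinom(300, 1, 0.4)
  scores <- labels + rnorm(300, sd = 0.8)
  a <- rocAuc(labels, scores)
  expect_equal(a$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(a$curve[nrow(a$curve), ]), c(1, 1))
  expect_true(all(diff(a$curve$fpr) >= 0) && all(diff(a$curve$tpr) >= 0))
  # curve trapezoid equals the rank-based AUC
  trap <- sum(diff(a$curve$fpr) *
                (head(a$curve$tpr, -1) + tail(a$curve$tpr, -1)) / 2)
  expect_equal(trap, a$auc, tolerance = 1e-12)

  perf <- rocAuc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perf$auc, 1)
  expect_identical(perf$class, "excellent")
  expect_identical(rocAuc(c(0, 1, 0, 1), c(1, 1, 1, 1))$class,
                   "no-better-than-random")
  expect_identical(rocAuc(rep(c(0, 1), 50),
                          rep(c(0.2, 0.6), 50))$class, "excellent")
  expect_error(rocAuc(rep(1, 10), runif(10)), "both classes")
})

test_that("AUC complement and monotone-transform invariances hold", {
  set.seed(13)
  labels <- rbinom(100, 1, 0.5)
  scores <- rnorm(100)                      # tie-free
  a1 <- rocAuc(labels, scores)$auc
  expect_equal(a1 + rocAuc(labels, -scores)$auc, 1, tolerance = 1e-12)
  expect_equal(rocAuc(labels, exp(scores))$auc, a1, tolerance = 1e-12)
  # rank statistics are invariant to monotone transforms of predictions
  coords <- cbind(runif(100), runif(100))
  obs <- rnorm(100)
  r1 <- correctedCorrelation(obs, scores, coords)
  r2 <- correctedCorrelation(obs, exp(scores), coords)
  expect_equal(r1$rS, r2$rS, tolerance = 1e-12)
})

test_that("evaluateModel reports both evaluations and the fallback rule", {
  fix <- recoverySurvey(seed = 14)
  sp <- suppressWarnings(splitTrainTest(fix$survey, seed = 3))
  fit <- fitHurdle(sp$train, "density_recov", c("depth", "sst"))
  rep <- evaluateModel(fit, sp$train, sp$test)
  expect_identical(rep$nTrain, 600L)
  expect_identical(rep$nTest, 300L)
  expect_s3_class(rep$internal, "CorrelationResult")
  expect_s3_class(rep$aucExternal, "AUCResult")
  # strong truth: internal correlation significant, no fallback
  expect_lt(rep$internal$pValue, 0.05)
  expect_false(rep$useBinomialOnly)
  path <- tempfile(fileext = ".csv")
  writeEvaluationCsv(rep, path)
  expect_true(file.exists(path))

  # shuffled predictions: external correlation non-significant -> fallback
  noisy <- fix$survey
  set.seed(4)
  noisy$density_recov <- sample(noisy$density_recov)
  spn <- suppressWarnings(splitTrainTest(noisy, seed = 5))
  fitn <- fitHurdle(spn$train, "density_recov", "depth")
  repn <- evaluateModel(fitn, spn$train, spn$test)
  expect_gt(repn$external$pValue, 0.001)   # no spurious ultra-significance
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- rbinom(500, 1, 0.35)
  scores <- labels * 0.6 + rnorm(500)
  ours <- rocAuc(labels, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
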