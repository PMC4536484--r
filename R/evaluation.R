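## Internal/external validation: train/test splitting with range-coverage
## checks, Spearman rank correlation corrected for spatial autocorrelation
## (modified t-test with Dutilleul's effective sample size, applied to
## ranks), and ROC/AUC with discrimination classes.

#' Random train/test split with range-coverage check
#'
#' Splits the survey rows into disjoint, exhaustive training (default 2/3)
#' and testing (1/3) sets. A coverage report states, per predictor and
#' response column, whether the test range lies within the training range
#' (so the evaluation never scores pure extrapolation); on a coverage
#' failure the split is redrawn with a new seed up to `maxRetries` times,
#' then returned with a warning.
#'
#' @param survey survey table (>= 30 rows).
#' @param ratio training fraction; `|train| = round(ratio * n)`.
#' @param seed integer RNG seed (reproducible splits).
#' @param predictors,responses columns entering the coverage check
#'   (defaults: the five predictors present, and all `density_*` +
#'   `richness` columns).
#' @param maxRetries resampling attempts on coverage failure.
#' @return list of class `trainTestSplit`: `train`, `test`, `trainIdx`,
#'   `coverage` (data.frame), `covered`, `seedUsed`, `attempts`.
#' @export
splitTrainTest <- function(survey, ratio = 2 / 3, seed = 1,
                           predictors = NULL, responses = NULL,
                           maxRetries = 20) {
  n <- nrow(survey)
  if (n < 30) stop("need at least 30 rows to split", call. = FALSE)
  if (is.null(predictors))
    predictors <- intersect(predictorNames(), names(survey))
  if (is.null(responses))
    responses <- intersect(c(grep("^density_", names(survey), value = TRUE),
                             "richness"), names(survey))
  cols <- c(predictors, responses)
  nTrain <- round(ratio * n)
  attempt <- 0L
  repeat {
    seedUsed <- seed + attempt
    set.seed(seedUsed)
    trainIdx <- sort(sample.int(n, nTrain))
    train <- survey[trainIdx, , drop = FALSE]
    test <- survey[-trainIdx, , drop = FALSE]
    cov <- data.frame(column = cols, covered = vapply(cols, function(cl) {
      tr <- range(train[[cl]], na.rm = TRUE)
      te <- range(test[[cl]], na.rm = TRUE)
      te[1L] >= tr[1L] && te[2L] <= tr[2L]
    }, logical(1)), row.names = NULL)
    if (all(cov$covered) || attempt >= maxRetries) break
    attempt <- attempt + 1L
  }
  if (!all(cov$covered))
    warning("test range exceeds training range for: ",
            paste(cov$column[!cov$covered], collapse = ", "),
            " after ", attempt + 1L, " attempts", call. = FALSE)
  structure(list(train = train, test = test, trainIdx = trainIdx,
                 coverage = cov, covered = all(cov$covered),
                 seedUsed = seedUsed, attempts = attempt + 1L),
            class = "trainTestSplit")
}

#' @export
print.trainTestSplit <- function(x, ...) {
  cat("trainTestSplit: ", nrow(x$train), " train / ", nrow(x$test),
      " test rows (seed ", x$seedUsed, ", coverage ",
      if (x$covered) "ok" else "FAILED", ")\n", sep = "")
  invisible(x)
}

## per-distance-class covariance matrix of a centred vector, used to build
## the spatial covariance estimate for the modified t-test
classCovarianceMatrix <- function(z, classIdx, nClasses, n) {
  zc <- z - mean(z)
  prod <- zc[classIdx$i] * zc[classIdx$j]
  classMean <- numeric(nClasses + 1L)
  sums <- rowsum(prod, classIdx$cl)
  cnts <- rowsum(rep(1, length(prod)), classIdx$cl)
  present <- as.integer(rownames(sums))
  classMean[present] <- sums / cnts
  classMean[nClasses + 1L] <- 0          # pairs beyond the maximum lag
  S <- matrix(0, n, n)
  S[cbind(classIdx$i, classIdx$j)] <- classMean[classIdx$cl]
  S <- S + t(S)
  diag(S) <- mean(zc^2)
  S
}

#' Spearman correlation corrected for spatial autocorrelation
#'
#' The modified t-test applied to rank-transformed data: the Spearman
#' coefficient is computed on ranks, the spatial covariance matrix of each
#' rank vector is estimated from an isotropic correlogram over equal-count
#' distance classes, and an effective sample size replaces `n` in the
#' t-test via the trace-ratio formula with the centring projector
#' `B = I - 11'/n`:
#' \deqn{\hat n_{eff} = 1 + \mathrm{tr}(B\Sigma_x)\,\mathrm{tr}(B\Sigma_y)
#'   / \mathrm{tr}(B\Sigma_x B\Sigma_y),}
#' then `t = r_s * sqrt((n_eff - 2) / (1 - r_s^2))` with `n_eff - 2`
#' degrees of freedom (two-sided). With no spatial autocorrelation the
#' correction vanishes (`n_eff` approaches `n`); positive autocorrelation
#' in both variables shrinks `n_eff` and inflates the p-value relative to
#' the uncorrected test. `n_eff` is clamped into `(2, n]`.
#'
#' Distance classes are equal-width over `[0, maxLagFrac * max distance]`
#' (the standard correlogram convention); pairs beyond the maximum lag
#' contribute zero covariance.
#'
#' @param x,y numeric vectors (length >= 10; neither constant).
#' @param coords two-column matrix/data.frame of planar station
#'   coordinates; duplicated locations are jittered slightly with a warning.
#' @param nClasses number of equal-width distance classes (default 10).
#' @param maxLagFrac maximum correlogram lag as a fraction of the maximum
#'   pairwise distance (default 1/2).
#' @return list of class `CorrelationResult`: `rS`, `n`, `nEff`, `t`, `df`,
#'   `pValue`, `pValueUncorrected`, `stars`, `nClasses`.
#' @export
correctedCorrelation <- function(x, y, coords, nClasses = 10,
                                 maxLagFrac = 0.5) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 10) stop("need at least 10 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (anyDuplicated(coords)) {
    warning("duplicated coordinates jittered", call. = FALSE)
    scale <- max(apply(coords, 2, function(v) diff(range(v))), 1)
    dup <- duplicated(coords)
    coords[dup, ] <- coords[dup, ] + runif(2 * sum(dup), -1, 1) * scale * 1e-6
  }
  rx <- rank(x); ry <- rank(y)
  rS <- stats::cor(rx, ry)
  D <- as.matrix(dist(coords))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  dvec <- D[iu]
  maxLag <- maxLagFrac * max(dvec)
  brk <- seq(0, maxLag, length.out = nClasses + 1)
  cl <- findInterval(dvec, brk, rightmost.closed = TRUE, all.inside = TRUE)
  cl[dvec > maxLag] <- nClasses + 1L    # beyond max lag: zero covariance
  classIdx <- list(i = iu[, 1L], j = iu[, 2L], cl = cl,
                   nClasses = nClasses)
  Sx <- classCovarianceMatrix(rx, classIdx, nClasses, n)
  Sy <- classCovarianceMatrix(ry, classIdx, nClasses, n)
  ## tr(B S) and tr(B Sx B Sy) with B = I - 11'/n applied analytically
  center <- function(S) S - matrix(colMeans(S), n, n, byrow = TRUE) -
    matrix(rowMeans(S), n, n) + mean(S)
  BSx <- center(Sx); BSy <- center(Sy)
  trX <- sum(diag(BSx)); trY <- sum(diag(BSy))
  trXY <- sum(BSx * t(BSy))
  nEff <- 1 + trX * trY / trXY
  if (!is.finite(nEff) || nEff <= 2) nEff <- 2 + 1e-6
  nEff <- min(nEff, n)
  tStat <- rS * sqrt((nEff - 2) / max(1 - rS^2, .Machine$double.eps))
  p <- if (abs(rS) >= 1) 0 else 2 * pt(-abs(tStat), df = nEff - 2)
  tRaw <- rS * sqrt((n - 2) / max(1 - rS^2, .Machine$double.eps))
  pRaw <- if (abs(rS) >= 1) 0 else 2 * pt(-abs(tRaw), df = n - 2)
  out <- list(rS = rS, n = n, nEff = nEff, t = tStat, df = nEff - 2,
              pValue = p, pValueUncorrected = pRaw,
              stars = significanceStars(p), nClasses = nClasses)
  class(out) <- "CorrelationResult"
  out
}

significanceStars <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf(
    "Spearman r_s = %.3f%s (n = %d, n_eff = %.1f, t = %.2f, p = %.4g)\n",
    x$rS, x$stars, x$n, x$nEff, x$t, x$pValue))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Area under the receiver operating characteristic curve by the
#' trapezoidal rule over all score thresholds, with tied scores given half
#' credit (equivalent to the rank-sum / pairwise-concordance formulation).
#' Discrimination classes: AUC <= 0.5 no better than random, (0.5, 0.7)
#' poor, \[0.7, 0.9\] very good, > 0.9 excellent.
#'
#' @param labels 0/1 vector (both classes required).
#' @param scores numeric prediction scores (higher = more likely positive).
#' @return list of class `AUCResult`: `auc`, `curve` (data.frame `fpr`,
#'   `tpr`, from (0,0) to (1,1)), `class`.
#' @export
rocAuc <- function(labels, scores) {
  labels <- as.integer(labels > 0)
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  lastOfTie <- c(diff(sc) != 0, TRUE)
  tpr <- cumsum(lab)[lastOfTie] / n1
  fpr <- cumsum(1 - lab)[lastOfTie] / n0
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  cls <- if (auc <= 0.5) "no-better-than-random"
         else if (auc < 0.7) "poor"
         else if (auc <= 0.9) "very good" else "excellent"
  structure(list(auc = auc, curve = curve, class = cls),
            class = "AUCResult")
}

#' @export
print.AUCResult <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%s), %d ROC points\n", x$auc, x$class,
              nrow(x$curve)))
  invisible(x)
}

#' Internal and external model evaluation
#'
#' Scores a fitted delta (or binomial-only) model on its own training data
#' (internal evaluation) and on held-out test data (external evaluation):
#' spatially corrected Spearman correlation between observed and predicted
#' values at the station coordinates, plus ROC/AUC of the occurrence
#' component on both sets. When the delta model's external correlation is
#' not significant at `alpha`, the report flags that only the binomial
#' occurrence model should be presented (`useBinomialOnly`).
#'
#' @param fit a [HurdleFit-class] trained on `train` only.
#' @param train,test survey tables from [splitTrainTest()].
#' @param response observed response column (defaults to the fit's).
#' @param coordCols coordinate column names (default `c("x", "y")`).
#' @param alpha significance level for the binomial-only decision rule.
#' @param nClasses distance classes for the spatial correction.
#' @return list of class `EvaluationReport`.
#' @export
evaluateModel <- function(fit, train, test, response = NULL,
                          coordCols = c("x", "y"), alpha = 0.05,
                          nClasses = 10) {
  stopifnot(is(fit, "HurdleFit"))
  if (is.null(response)) response <- fit@occurrence@response
  predictFor <- function(dat) {
    if (fit@mode == "delta") as.numeric(predictDelta(fit, dat))
    else as.numeric(predictComponent(fit@occurrence, dat))
  }
  obsTr <- train[[response]]; obsTe <- test[[response]]
  prTr <- predictFor(train); prTe <- predictFor(test)
  internal <- correctedCorrelation(obsTr, prTr,
                                   train[, coordCols], nClasses)
  external <- correctedCorrelation(obsTe, prTe,
                                   test[, coordCols], nClasses)
  occTr <- as.numeric(predictComponent(fit@occurrence, train))
  occTe <- as.numeric(predictComponent(fit@occurrence, test))
  aucFor <- function(obs, pr, which) {
    lab <- as.integer(obs > 0)
    if (length(unique(lab)) < 2L) {
      warning("AUC skipped (single class) for ", which, " set",
              call. = FALSE)
      return(NULL)
    }
    rocAuc(lab, pr)
  }
  aucInternal <- aucFor(obsTr, occTr, "training")
  aucExternal <- aucFor(obsTe, occTe, "testing")
  useBinomialOnly <- fit@mode == "delta" &&
    (!is.finite(external$pValue) || external$pValue > alpha)
  out <- list(response = response, mode = fit@mode,
              internal = internal, external = external,
              aucInternal = aucInternal, aucExternal = aucExternal,
              nTrain = nrow(train), nTest = nrow(test),
              alpha = alpha, useBinomialOnly = useBinomialOnly)
  class(out) <- "EvaluationReport"
  out
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport:", x$response, "(", x$mode, "model,",
      x$nTrain, "train /", x$nTest, "test )\n  internal ")
  print(x$internal)
  cat("  external ")
  print(x$external)
  if (!is.null(x$aucInternal))
    cat(sprintf("  AUC internal %.3f (%s), external %s\n",
                x$aucInternal$auc, x$aucInternal$class,
                if (is.null(x$aucExternal)) "skipped"
                else sprintf("%.3f (%s)", x$aucExternal$auc,
                             x$aucExternal$class)))
  if (x$useBinomialOnly)
    cat("  NOTE: delta model externally non-significant at alpha =",
        x$alpha, "-> present binomial occurrence model only\n")
  invisible(x)
}

#' Flatten an evaluation report to one CSV row
#'
#' @param x an `EvaluationReport`.
#' @param path output CSV path.
#' @export
writeEvaluationCsv <- function(x, path) {
  stopifnot(inherits(x, "EvaluationReport"))
  row <- data.frame(
    response = x$response, mode = x$mode, nTrain = x$nTrain,
    nTest = x$nTest,
    rS_internal = x$internal$rS, stars_internal = x$internal$stars,
    p_internal = x$internal$pValue, nEff_internal = x$internal$nEff,
    rS_external = x$external$rS, stars_external = x$external$stars,
    p_external = x$external$pValue, nEff_external = x$external$nEff,
    auc_internal = if (is.null(x$aucInternal)) NA else x$aucInternal$auc,
    auc_external = if (is.null(x$aucExternal)) NA else x$aucExternal$auc,
    use_binomial_only = x$useBinomialOnly)
  write.csv(row, path, row.names = FALSE)
  invisible(path)
}
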