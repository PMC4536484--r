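## Collinearity screening, candidate-model enumeration and ranking by
## small-sample-corrected AIC (AICc), with Akaike weights and the
## delta-AICc <= 2 competing set.

#' Small-sample-corrected Akaike Information Criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts the
#' model's effective parameters (for penalized smooths, the total effective
#' degrees of freedom including the intercept and any estimated dispersion)
#' and `n` the observations. Reduces to AIC as `n` grows.
#'
#' @param logLik maximized log-likelihood.
#' @param k effective number of parameters (`n > k + 1` required).
#' @param n number of observations.
#' @return the AICc value (vectorized over the inputs).
#' @examples
#' aicc(-22, 3, 100)  # 50 + 24/96 = 50.25
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1))
    stop("AICc correction undefined: need n > k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' The scaled likelihood that each candidate is the best description of the
#' data: `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with `Delta_i` the
#' AICc difference to the best candidate. Weights sum to 1, lower AICc
#' gives higher weight, and adding a constant to all AICc values changes
#' nothing.
#'
#' @param aiccValues numeric vector of AICc values (NA allowed; weight NA).
#' @return numeric vector of weights.
#' @export
akaikeWeights <- function(aiccValues) {
  ok <- is.finite(aiccValues)
  if (!any(ok)) stop("no finite AICc values", call. = FALSE)
  d <- aiccValues - min(aiccValues[ok])
  w <- exp(-d / 2)
  w[!ok] <- NA_real_
  w / sum(w[ok])
}

#' Variance-inflation-factor collinearity screen
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from an ordinary least-squares
#' regression of predictor `j` on the remaining predictors. Exact linear
#' dependence yields an infinite VIF and a failed screen.
#'
#' @param data data.frame of rows (at least `length(predictors) + 2`).
#' @param predictors predictor column names (default the five environmental
#'   predictors).
#' @param threshold pass threshold: all VIF must be strictly below it
#'   (default 2).
#' @return an object of class `VifReport`: `table` (predictor, vif), `pass`,
#'   `threshold`.
#' @export
vifScreen <- function(data, predictors = predictorNames(), threshold = 2) {
  stopifnot(length(predictors) >= 2)
  if (nrow(data) < length(predictors) + 2)
    stop("need at least length(predictors) + 2 rows", call. = FALSE)
  X <- as.data.frame(data)[, predictors, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  vif <- vapply(seq_along(predictors), function(j) {
    fml <- stats::as.formula(paste(predictors[j], "~",
                                   paste(predictors[-j], collapse = " + ")))
    r2 <- summary(lm(fml, data = X))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- list(table = data.frame(predictor = predictors, vif = vif),
              pass = all(is.finite(vif)) && all(vif < threshold),
              threshold = threshold)
  class(out) <- "VifReport"
  out
}

#' @export
print.VifReport <- function(x, ...) {
  cat("VIF collinearity screen (threshold", x$threshold, "):",
      if (x$pass) "PASS" else "FAIL", "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

termSubsets <- function(terms) {
  n <- length(terms)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(grid)), function(i) terms[unlist(grid[i, ])])
}

candidateRow <- function(terms, allTerms, cf, err = NULL, n = NA_integer_) {
  flags <- as.list(setNames(allTerms %in% terms, allTerms))
  if (is.null(cf)) {
    data.frame(flags, nTerms = length(terms), k = NA_real_,
               logLik = NA_real_, AICc = NA_real_, devExplained = NA_real_,
               adjR2 = NA_real_, fitted = FALSE,
               error = conditionMessage(err), check.names = FALSE)
  } else {
    data.frame(flags, nTerms = length(terms), k = cf@edf, logLik = cf@logLik,
               AICc = aicc(cf@logLik, cf@edf, cf@n),
               devExplained = cf@devianceExplained, adjR2 = cf@adjR2,
               fitted = TRUE, error = "", check.names = FALSE)
  }
}

#' All-subsets (or backward) model selection by AICc
#'
#' Fits candidate term subsets for one delta-model component via
#' [fitComponent()] and ranks them by AICc. The default scheme enumerates
#' all subsets of the candidate terms plus the intercept-only model (32
#' candidates for five terms), removing the path dependence of stepwise
#' search; `"backward"` eliminates terms one at a time from the full model
#' while AICc improves. Ties are broken by fewer effective parameters, then
#' lexicographic term order. Candidates whose fit fails are recorded and
#' excluded from the ranking. The procedure is deterministic given the data.
#'
#' @inheritParams fitComponent
#' @param terms candidate predictor names.
#' @param scheme `"all_subsets"` (default) or `"backward"`.
#' @return a [SelectionTable-class]; `@bestFit` holds the best candidate's
#'   [ComponentFit-class].
#' @export
selectModel <- function(data, response, part = c("occurrence", "positive"),
                        terms = predictorNames(),
                        scheme = c("all_subsets", "backward"),
                        k = 5, bs = "cs", method = "REML", gamma = 1.4) {
  part <- match.arg(part)
  scheme <- match.arg(scheme)
  fitOne <- function(tm) tryCatch(
    fitComponent(data, response, part, tm, k = k, bs = bs, method = method,
                 gamma = gamma),
    error = function(e) e)
  cands <- if (scheme == "all_subsets") termSubsets(terms)
           else backwardPath(data, response, part, terms, k, bs, method,
                             gamma)
  fits <- lapply(cands, fitOne)
  rows <- mapply(function(tm, cf) {
    if (inherits(cf, "error")) candidateRow(tm, terms, NULL, err = cf)
    else candidateRow(tm, terms, cf)
  }, cands, fits, SIMPLIFY = FALSE)
  tb <- do.call(rbind, rows)
  tb$termSet <- vapply(cands, function(tm)
    if (length(tm)) paste(sort(tm), collapse = "+") else "(intercept)",
    character(1))
  ord <- order(!tb$fitted, tb$AICc, tb$k, tb$termSet)
  tb <- tb[ord, , drop = FALSE]
  fits <- fits[ord]
  rownames(tb) <- NULL
  ok <- which(tb$fitted)
  tb$deltaAICc <- tb$AICc - min(tb$AICc[ok])
  tb$weight <- NA_real_
  tb$weight[ok] <- akaikeWeights(tb$AICc[ok])
  best <- ok[1L]
  competing <- ok[tb$deltaAICc[ok] <= 2]
  new("SelectionTable", table = tb, bestIndex = as.integer(best),
      competing = as.integer(competing), part = part, response = response,
      bestFit = fits[[best]])
}

## backward-elimination candidate path (records every model visited)
backwardPath <- function(data, response, part, terms, k, bs, method,
                         gamma) {
  aiccOf <- function(tm) {
    cf <- tryCatch(fitComponent(data, response, part, tm, k = k, bs = bs,
                                method = method, gamma = gamma),
                   error = function(e) NULL)
    if (is.null(cf)) Inf else aicc(cf@logLik, cf@edf, cf@n)
  }
  visited <- list(terms)
  current <- terms
  currentAicc <- aiccOf(current)
  repeat {
    if (!length(current)) break
    drops <- lapply(seq_along(current), function(i) current[-i])
    vals <- vapply(drops, aiccOf, numeric(1))
    visited <- c(visited, drops)
    if (min(vals) < currentAicc) {
      current <- drops[[which.min(vals)]]
      currentAicc <- min(vals)
    } else break
  }
  unique(visited)
}

setMethod("show", "SelectionTable", function(object) {
  tb <- object@table
  cat("SelectionTable [", object@part, "] response:", object@response,
      "-", nrow(tb), "candidates,", length(object@competing),
      "competing (deltaAICc <= 2)\n")
  cols <- c("termSet", "k", "AICc", "deltaAICc", "weight", "devExplained",
            "adjR2")
  print(head(tb[, cols], 8), row.names = FALSE, digits = 4)
  if (nrow(tb) > 8) cat("  ...", nrow(tb) - 8, "more rows\n")
})

#' @rdname selectModel
#' @param x a [SelectionTable-class].
#' @export
competingModels <- function(x) {
  stopifnot(is(x, "SelectionTable"))
  x@table[x@competing, , drop = FALSE]
}

#' @rdname selectModel
#' @export
bestModel <- function(x) {
  stopifnot(is(x, "SelectionTable"))
  x@bestFit
}

#' Write a selection table to CSV
#'
#' One row per candidate with per-term inclusion flags, AICc, delta-AICc,
#' Akaike weight, percent deviance explained and adjusted R-squared.
#'
#' @param x a [SelectionTable-class].
#' @param path output CSV path.
#' @export
writeSelectionCsv <- function(x, path) {
  stopifnot(is(x, "SelectionTable"))
  write.csv(x@table, path, row.names = FALSE)
  invisible(path)
}
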