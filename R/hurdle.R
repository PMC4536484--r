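## Two-part (delta/hurdle) generalized additive models: a binomial-logit
## occurrence component and a negative-binomial log-link positive-abundance
## component fitted on the strictly positive subset; final predictions are
## the elementwise product of the two component predictions.

componentFamilyLabel <- function(part)
  if (part == "occurrence") "binomial-logit" else "negative-binomial-log"

buildSmoothFormula <- function(terms, k, bs) {
  if (!length(terms)) return(stats::as.formula(".y ~ 1"))
  rhs <- paste(sprintf("s(%s, k = %d, bs = \"%s\")", terms, k, bs),
               collapse = " + ")
  stats::as.formula(paste(".y ~", rhs))
}

#' Fit one component of a delta model
#'
#' Fits a generalized additive model in which each predictor enters as a
#' univariate penalized cubic regression spline (shrinkage basis `"cs"`,
#' basis dimension `k = 5` by default), with smoothness selected by REML.
#' The occurrence part binarises the response (`> 0`) and uses a binomial
#' family with logit link; the positive part restricts the data to strictly
#' positive responses and uses a negative-binomial family with log link
#' (dispersion estimated from the data), accommodating zero-inflated,
#' overdispersed survey densities.
#'
#' @param data survey rows (data.frame) containing `response` and `terms`.
#' @param response response column name (a `density_*` column, `richness`,
#'   or any nonnegative column; 0/1 presence columns work for the
#'   occurrence part).
#' @param part `"occurrence"` or `"positive"`.
#' @param terms character vector of predictor names (possibly empty:
#'   intercept-only model).
#' @param k spline basis dimension per term.
#' @param bs [mgcv::smooth.terms] basis code (default `"cs"`, shrinkage
#'   cubic regression spline).
#' @param method smoothing-parameter selection criterion passed to
#'   [mgcv::gam()] (default `"REML"`).
#' @param gamma smoothing-penalty inflation factor (default 1.4, the
#'   standard guard against occasional overfitting in automatic smoothness
#'   selection).
#' @return a [ComponentFit-class]. Effective degrees of freedom (`@edf`)
#'   total the smoothing-uncertainty-corrected effective df of the fit
#'   (the quantity mgcv's conditional AIC uses) including the intercept,
#'   plus one for the estimated negative-binomial dispersion.
#' @export
fitComponent <- function(data, response, part = c("occurrence", "positive"),
                         terms = character(), k = 5, bs = "cs",
                         method = "REML", gamma = 1.4) {
  part <- match.arg(part)
  if (!response %in% names(data))
    stop("response column '", response, "' not found", call. = FALSE)
  miss <- setdiff(terms, names(data))
  if (length(miss))
    stop("missing predictor columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  yRaw <- data[[response]]
  if (part == "occurrence") {
    y <- as.numeric(yRaw > 0)
    keep <- !is.na(y)
    if (length(unique(y[keep])) < 2L)
      stop("degenerate response: all observations ",
           if (all(y[keep] == 1)) "present" else "absent", call. = FALSE)
    fam <- stats::binomial(link = "logit")
  } else {
    keep <- !is.na(yRaw) & yRaw > 0
    if (sum(keep) < max(10 * length(terms), 10))
      stop("insufficient positive observations (", sum(keep), ") for ",
           length(terms), " smooth terms", call. = FALSE)
    y <- yRaw
    fam <- mgcv::nb()
  }
  df <- data[keep, c(terms), drop = FALSE]
  df$.y <- y[keep]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  fit <- mgcv::gam(buildSmoothFormula(terms, k, bs), family = fam,
                   data = df, method = method, gamma = gamma)
  sm <- summary(fit)
  ## corrected effective df (accounts for smoothing-parameter uncertainty)
  edfVec <- if (is.null(fit$edf2)) fit$edf else fit$edf2
  edf <- sum(edfVec) + if (part == "positive") 1 else 0
  ## constant responses have (numerically) zero null deviance: nothing
  ## explainable, whatever the deviance ratio says
  devExpl <- 100 * sm$dev.expl
  if (!is.finite(devExpl) || sd(df$.y) == 0) devExpl <- 0
  new("ComponentFit", part = part, response = response,
      family = componentFamilyLabel(part), terms = as.character(terms),
      fit = fit, n = nrow(df), logLik = as.numeric(logLik(fit)),
      ## shrinkage fits can report marginally negative dev.expl; clamp
      edf = edf, devianceExplained = min(max(devExpl, 0), 100),
      adjR2 = as.numeric(sm$r.sq),
      trainRanges = lapply(df[, terms, drop = FALSE], range))
}

#' Predict from one delta-model component
#'
#' Response-scale predictions (occurrence probabilities in \[0,1\], or
#' conditional mean densities > 0). Rows whose predictor values fall
#' outside the component's training range are predicted anyway
#' (extrapolation) but flagged in the `"extrapolated"` attribute.
#'
#' @param fit a [ComponentFit-class].
#' @param newdata data.frame with the fit's term columns, or an
#'   [EnvironmentGrid-class] (delegates to [predictRaster()]).
#' @return numeric vector with logical attribute `extrapolated`, or a
#'   [PredictionRaster-class] for grid input.
#' @export
predictComponent <- function(fit, newdata) {
  stopifnot(is(fit, "ComponentFit"))
  if (is(newdata, "EnvironmentGrid")) return(predictRaster(fit, newdata))
  miss <- setdiff(fit@terms, names(newdata))
  if (length(miss))
    stop("newdata lacks predictor columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  nd <- as.data.frame(newdata)[, fit@terms, drop = FALSE]
  if (!length(fit@terms))
    nd <- data.frame(.dummy = rep(1, nrow(as.data.frame(newdata))))
  pr <- as.numeric(predict(fit@fit, newdata = nd, type = "response"))
  extra <- rep(FALSE, nrow(nd))
  for (tm in fit@terms) {
    rg <- fit@trainRanges[[tm]]
    extra <- extra | nd[[tm]] < rg[1L] | nd[[tm]] > rg[2L]
  }
  attr(pr, "extrapolated") <- extra
  pr
}

#' Fit a full delta (hurdle) model
#'
#' Fits the binomial occurrence component on all rows and the
#' negative-binomial positive component on the strictly positive subset of
#' the same data (the positive component never sees zero-density rows).
#'
#' @inheritParams fitComponent
#' @param termsOccurrence,termsPositive term sets for the two parts
#'   (independent per-part selection is the package's convention).
#' @param mode `"delta"` (default) or `"binomial_only"` (no positive part).
#' @return a [HurdleFit-class].
#' @export
fitHurdle <- function(data, response, termsOccurrence,
                      termsPositive = termsOccurrence,
                      mode = c("delta", "binomial_only"), k = 5, bs = "cs",
                      method = "REML", gamma = 1.4) {
  mode <- match.arg(mode)
  occ <- fitComponent(data, response, "occurrence", termsOccurrence,
                      k = k, bs = bs, method = method, gamma = gamma)
  pos <- NULL
  if (mode == "delta")
    pos <- fitComponent(data, response, "positive", termsPositive,
                        k = k, bs = bs, method = method, gamma = gamma)
  new("HurdleFit", occurrence = occ, positive = pos, mode = mode)
}

#' Combined delta-model prediction
#'
#' The preferential-habitat prediction: the occurrence probability
#' multiplied elementwise by the conditional positive density,
#' `p_hat * mu_hat`; nonnegative, and exactly zero wherever `p_hat` is 0.
#'
#' @param fit a [HurdleFit-class] with `mode = "delta"`.
#' @param newdata data.frame of predictors or an [EnvironmentGrid-class].
#' @return numeric vector (with `extrapolated` attribute) or a
#'   [PredictionRaster-class].
#' @export
predictDelta <- function(fit, newdata) {
  stopifnot(is(fit, "HurdleFit"))
  if (fit@mode != "delta")
    stop("fit has mode 'binomial_only'; use predictComponent(fit@occurrence, ...)",
         call. = FALSE)
  if (is(newdata, "EnvironmentGrid")) return(predictRaster(fit, newdata))
  p <- predictComponent(fit@occurrence, newdata)
  m <- predictComponent(fit@positive, newdata)
  out <- as.numeric(p) * as.numeric(m)
  attr(out, "extrapolated") <- attr(p, "extrapolated") | attr(m, "extrapolated")
  out
}

#' Evaluate a fitted partial smooth effect
#'
#' Returns the centred partial effect of one term over its training range,
#' with pointwise 95% confidence bands, for effect-shape plots.
#'
#' @param fit a [ComponentFit-class].
#' @param term one of `fit@terms`.
#' @param n evaluation points.
#' @return data.frame with `value`, `effect`, `lower`, `upper` (link scale).
#' @export
smoothEffect <- function(fit, term, n = 200) {
  stopifnot(is(fit, "ComponentFit"))
  if (!term %in% fit@terms)
    stop("term '", term, "' not in fit", call. = FALSE)
  rg <- fit@trainRanges[[term]]
  nd <- as.data.frame(lapply(fit@trainRanges, function(r) rep(mean(r), n)))
  nd[[term]] <- seq(rg[1L], rg[2L], length.out = n)
  pr <- predict(fit@fit, newdata = nd, type = "terms", se.fit = TRUE)
  colIdx <- grep(paste0("s\\(", term, "\\)"), colnames(pr$fit))
  data.frame(value = nd[[term]], effect = pr$fit[, colIdx],
             lower = pr$fit[, colIdx] - 1.96 * pr$se.fit[, colIdx],
             upper = pr$fit[, colIdx] + 1.96 * pr$se.fit[, colIdx])
}

setMethod("show", "ComponentFit", function(object) {
  cat("ComponentFit [", object@part, "] response:", object@response,
      "\n  family:", object@family,
      "\n  terms:", if (length(object@terms))
        paste(object@terms, collapse = ", ") else "(intercept only)",
      "\n  n:", object@n, " edf:", round(object@edf, 2),
      " deviance explained:", round(object@devianceExplained, 1),
      "%  adj-R2:", round(object@adjR2, 3), "\n")
})

setMethod("show", "HurdleFit", function(object) {
  cat("HurdleFit mode:", object@mode, "\n")
  show(object@occurrence)
  if (is(object@positive, "ComponentFit")) show(object@positive)
})
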