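#' Fitted traffic (hazard) submodel
#'
#' A random-forest regression predicting either traffic volume (AADT,
#' modeled on the log scale because AADT is approximately log-normal) or
#' posted speed (identity scale) for every road segment.
#'
#' @slot model the fitted \code{randomForest}.
#' @slot predictorNames predictors used, after pruning.
#' @slot responseTransform "log" (volume) or "identity" (speed).
#' @slot nTrees forest size (default 500).
#' @slot pctVarianceExplained out-of-bag percent variance explained,
#'   \eqn{100 (1 - MSE_{oob} / \mathrm{var}(y))}.
#' @slot importance per-variable percent importance, sums to 100.
#' @slot smearingFactor Duan smearing factor for back-transformed volume
#'   predictions (1 when the correction is off).
#' @export
setClass("TrafficFit",
  representation(model = "ANY", predictorNames = "character",
                 responseTransform = "character", nTrees = "integer",
                 pctVarianceExplained = "numeric", importance = "numeric",
                 smearingFactor = "numeric"),
  validity = function(object) {
    if (!object@responseTransform %in% c("log", "identity"))
      return("responseTransform must be \"log\" or \"identity\"")
    if (object@nTrees < 1L) return("nTrees must be >= 1")
    if (length(object@importance) &&
        abs(sum(object@importance) - 100) > 0.1)
      return("importance must sum to 100%")
    TRUE
  })

setMethod("show", "TrafficFit", function(object) {
  cat(sprintf(
    "TrafficFit (%s response): %d trees, OOB variance explained %.1f%%\n",
    object@responseTransform, object@nTrees, object@pctVarianceExplained))
  cat("  importance (%):",
      paste(sprintf("%s %.1f", names(object@importance),
                    object@importance), collapse = ", "), "\n")
})

#' @rdname TrafficFit-class
#' @param x a \code{TrafficFit}.
#' @export
pctVarianceExplained <- function(x) x@pctVarianceExplained

#' @rdname TrafficFit-class
#' @export
variableImportance <- function(x) x@importance

trafficForest <- function(train, response, predictors, transform,
                          nTrees, seed, smearing = FALSE) {
  miss <- setdiff(c(response, predictors), names(train))
  if (length(miss))
    stop("missing training column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- train[[response]]
  checkPositive(y, response, train$segment_id)
  yt <- if (transform == "log") log(y) else y
  X <- train[, predictors, drop = FALSE]
  rf <- withSubSeed(seed, paste0("forest-", response),
                    randomForest::randomForest(x = X, y = yt,
                                               ntree = nTrees,
                                               importance = TRUE))
  pct <- 100 * rf$rsq[nTrees]
  imp <- rf$importance[, "IncNodePurity"]
  imp <- 100 * imp / sum(imp)
  smear <- 1
  if (transform == "log" && smearing)
    smear <- mean(exp(yt - rf$predicted))
  new("TrafficFit", model = rf, predictorNames = predictors,
      responseTransform = transform, nTrees = as.integer(nTrees),
      pctVarianceExplained = pct, importance = imp,
      smearingFactor = smear)
}

#' Fit the traffic-volume submodel
#'
#' Random-forest regression of ln(AADT) on the demand-related predictors
#' (distance to development, distance to major roads, population density,
#' road-class intensity, road density), after pruning predictors whose
#' pairwise correlation reaches \code{corThreshold} (0.7 for the traffic
#' models). Back-transformed predictions are vehicles/day.
#'
#' @param train data.frame with column \code{AADT} (> 0) and the
#'   predictors.
#' @param predictors candidate predictor names.
#' @param corThreshold correlation-pruning threshold (default 0.7).
#' @param nTrees forest size (default 500).
#' @param smearing apply Duan's smearing correction when back-transforming
#'   (default FALSE: plain exponentiation).
#' @param seed integer seed.
#' @return a \linkS4class{TrafficFit} with log response.
#' @export
fitVolumeModel <- function(train,
                           predictors = c("KMTODEV", "KMTOHWY", "POPDENS",
                                          "RDCLASS", "RDDENS"),
                           corThreshold = 0.7, nTrees = 500L,
                           smearing = FALSE, seed = 1L) {
  pruned <- correlationPrune(train[, predictors, drop = FALSE],
                             threshold = corThreshold)
  trafficForest(train, "AADT", names(pruned$table), "log", nTrees, seed,
                smearing = smearing)
}

#' Fit the traffic-speed submodel
#'
#' Random-forest regression of the posted speed limit on road-class
#' intensity and road density (the two speed predictors), identity
#' response.
#'
#' @param train data.frame with column \code{SPEEDLMT} (> 0), plus
#'   \code{RDCLASS} and \code{RDDENS}.
#' @param predictors predictor names (default RDCLASS, RDDENS).
#' @param nTrees forest size (default 500).
#' @param seed integer seed.
#' @return a \linkS4class{TrafficFit} with identity response.
#' @export
fitSpeedModel <- function(train, predictors = c("RDCLASS", "RDDENS"),
                          nTrees = 500L, seed = 1L) {
  trafficForest(train, "SPEEDLMT", predictors, "identity", nTrees, seed)
}

#' Predict traffic volume or speed for road segments
#'
#' Volume predictions are exponentiated back to vehicles/day (strictly
#' positive, times the smearing factor if enabled at fit time); speed
#' predictions are km/h and stay within the range of the training speeds
#' (forest predictions are averages of observed responses).
#'
#' @param fit a \linkS4class{TrafficFit}.
#' @param segments data.frame carrying all predictor columns.
#' @return numeric vector of per-segment predictions.
#' @export
predictTraffic <- function(fit, segments) {
  miss <- setdiff(fit@predictorNames, names(segments))
  if (length(miss))
    stop("missing predictor field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  p <- as.numeric(predict(fit@model,
                          segments[, fit@predictorNames, drop = FALSE]))
  if (fit@responseTransform == "log") exp(p) * fit@smearingFactor else p
}
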