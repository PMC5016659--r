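#' Build a presence/background training table
#'
#' Samples every covariate raster at the presence and background points,
#' labels rows 1/0, and drops rows falling in no-data cells (null values
#' are eliminated after sampling).
#'
#' @param presences,background data.frames with columns \code{x}, \code{y}.
#' @param rasters named list of \linkS4class{CovariateRaster}.
#' @return data.frame with a binary \code{label} column followed by one
#'   column per covariate.
#' @export
buildOccurrenceTraining <- function(presences, background, rasters) {
  pts <- rbind(presences[, c("x", "y")], background[, c("x", "y")])
  tab <- data.frame(label = rep(c(1L, 0L),
                                c(nrow(presences), nrow(background))))
  for (nm in names(rasters))
    tab[[nm]] <- sampleRasterAtPoints(rasters[[nm]], pts$x, pts$y)
  tab[stats::complete.cases(tab), , drop = FALSE]
}

#' Prune collinear covariates
#'
#' Greedy removal of covariates until every pairwise |Pearson r| is below
#' the threshold: at each step the most-correlated offending pair is found
#' and the member with the larger mean absolute correlation to all other
#' remaining covariates is dropped. Constant columns (undefined
#' correlation) are dropped first with a warning. Deterministic.
#'
#' @param table data.frame of numeric covariates (a \code{label} column, if
#'   present, is carried through untouched).
#' @param threshold correlation threshold in (0, 1]; 0.75 for the
#'   occurrence covariates, 0.7 for the traffic predictors.
#' @return list with \code{table} (pruned) and \code{dropped} (names).
#' @export
correlationPrune <- function(table, threshold = 0.75) {
  stopIfNot(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  keepCols <- setdiff(names(table), "label")
  dropped <- character(0)
  isConst <- vapply(table[keepCols], function(x) sd(x) == 0 || !is.numeric(x),
                    TRUE)
  if (any(isConst)) {
    warning("dropping constant column(s): ",
            paste(keepCols[isConst], collapse = ", "), call. = FALSE)
    dropped <- keepCols[isConst]
    keepCols <- keepCols[!isConst]
  }
  repeat {
    if (length(keepCols) < 2L) break
    r <- abs(stats::cor(table[keepCols]))
    diag(r) <- 0
    if (max(r) < threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    pair <- keepCols[worst]
    meanAbs <- rowMeans(r[pair, , drop = FALSE])
    # drop the pair member with larger mean |r|; ties drop the later column
    victim <- if (meanAbs[1L] > meanAbs[2L]) pair[1L] else pair[2L]
    dropped <- c(dropped, victim)
    keepCols <- setdiff(keepCols, victim)
  }
  keep <- intersect(names(table), c("label", keepCols))
  list(table = table[, keep, drop = FALSE], dropped = dropped)
}

#' Fitted occurrence (exposure) submodel
#'
#' A boosted classification-tree ensemble relating species presence to the
#' environmental covariates, with its evaluation metrics.
#'
#' @slot model the fitted booster.
#' @slot featureNames covariates used, in training order.
#' @slot nTrees ensemble size selected by cross-validation.
#' @slot treeComplexity terminal-node limit per tree.
#' @slot learningRate per-tree shrinkage.
#' @slot devianceExplained percent of null deviance explained (training).
#' @slot cvAuc c(mean, sd) of the cross-validated AUC.
#' @slot contributions per-variable percent contribution, sums to 100.
#' @slot partialDependence named list of data.frames (value, response).
#' @export
setClass("OccurrenceFit",
  representation(model = "ANY", featureNames = "character",
                 nTrees = "integer", treeComplexity = "integer",
                 learningRate = "numeric", devianceExplained = "numeric",
                 cvAuc = "numeric", contributions = "numeric",
                 partialDependence = "list"),
  validity = function(object) {
    if (length(object@contributions) &&
        abs(sum(object@contributions) - 100) > 0.1)
      return("contributions must sum to 100%")
    if (any(object@cvAuc[1L] < 0 | object@cvAuc[1L] > 1))
      return("cv AUC must lie in [0, 1]")
    TRUE
  })

setMethod("show", "OccurrenceFit", function(object) {
  cat(sprintf(
    "OccurrenceFit: %d trees (complexity %d, learning rate %g)\n  deviance explained %.1f%%, CV AUC %.3f +/- %.3f\n",
    object@nTrees, object@treeComplexity, object@learningRate,
    object@devianceExplained, object@cvAuc[1L], object@cvAuc[2L]))
  cat("  contributions (%):",
      paste(sprintf("%s %.1f", names(object@contributions),
                    object@contributions), collapse = ", "), "\n")
})

#' @rdname OccurrenceFit-class
#' @param x an \code{OccurrenceFit}.
#' @export
cvAuc <- function(x) x@cvAuc

#' @rdname OccurrenceFit-class
#' @export
variableContributions <- function(x) x@contributions

#' @rdname OccurrenceFit-class
#' @export
partialDependence <- function(x) x@partialDependence

binomialDeviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Fit the species-occurrence submodel (boosted trees)
#'
#' Stagewise gradient-boosted classification trees on presence/background
#' data: small trees (terminal-node limit \code{treeComplexity}) added with
#' shrinkage \code{learningRate} and row subsampling \code{bagFraction}.
#' The ensemble size is chosen by k-fold cross-validated deviance
#' minimization with early stopping; cross-validated AUC is recorded from
#' the held-out folds at the selected size.
#'
#' @param train training table from \code{\link{buildOccurrenceTraining}}
#'   (after \code{\link{correlationPrune}}).
#' @param treeComplexity terminal-node limit per tree (default 5).
#' @param learningRate per-tree shrinkage (default 0.005).
#' @param bagFraction stochastic row-subsampling rate (default 0.5).
#' @param nFolds cross-validation folds (default 10).
#' @param maxTrees ceiling on ensemble size (default 3000).
#' @param earlyStopping rounds without CV improvement before stopping.
#' @param seed integer seed controlling folds and subsampling.
#' @return an \linkS4class{OccurrenceFit}.
#' @export
fitOccurrence <- function(train, treeComplexity = 5L, learningRate = 0.005,
                          bagFraction = 0.5, nFolds = 10L, maxTrees = 3000L,
                          earlyStopping = 50L, seed = 1L) {
  y <- train$label
  stopIfNot(length(unique(y)) == 2L,
            "both presence and background labels are required to fit")
  feats <- setdiff(names(train), "label")
  X <- as.matrix(train[, feats, drop = FALSE])
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  params <- list(objective = "binary:logistic",
                 eta = learningRate,
                 tree_method = "hist", grow_policy = "lossguide",
                 max_depth = 0L, max_leaves = as.integer(treeComplexity),
                 subsample = bagFraction, nthread = 1L,
                 seed = subSeed(seed, "brt-internal"))
  # early stopping minimizes the last metric: the CV deviance (logloss)
  cv <- withSubSeed(seed, "brt-cv",
    xgboost::xgb.cv(params = params, data = dtrain,
                    nrounds = maxTrees, nfold = nFolds,
                    metrics = list("auc", "logloss"),
                    early_stopping_rounds = earlyStopping,
                    stratified = TRUE, verbose = 0))
  best <- cv$early_stop$best_iteration
  if (is.null(best) || is.na(best)) best <- cv$niter
  log <- cv$evaluation_log
  cvauc <- c(mean = log$test_auc_mean[best], sd = log$test_auc_std[best])
  booster <- withSubSeed(seed, "brt-fit",
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = best, verbose = 0))
  p <- predict(booster, X)
  nullDev <- binomialDeviance(y, rep(mean(y), length(y)))
  devExp <- 100 * (nullDev - binomialDeviance(y, p)) / nullDev
  imp <- xgboost::xgb.importance(model = booster)
  contrib <- setNames(rep(0, length(feats)), feats)
  contrib[imp$Feature] <- imp$Gain
  contrib <- 100 * contrib / sum(contrib)
  pd <- partialDependenceCurves(booster, X)
  new("OccurrenceFit", model = booster, featureNames = feats,
      nTrees = as.integer(best),
      treeComplexity = as.integer(treeComplexity),
      learningRate = learningRate,
      devianceExplained = devExp, cvAuc = cvauc,
      contributions = contrib, partialDependence = pd)
}

# Partial dependence: response over a grid of one covariate with the
# others averaged over (a subsample of) the training rows.
partialDependenceCurves <- function(booster, X, nGrid = 25L,
                                    maxRows = 400L) {
  rows <- if (nrow(X) > maxRows)
    round(seq(1L, nrow(X), length.out = maxRows)) else seq_len(nrow(X))
  Xs <- X[rows, , drop = FALSE]
  out <- lapply(colnames(X), function(nm) {
    grid <- unique(quantile(X[, nm], probs = seq(0.02, 0.98,
                                                 length.out = nGrid)))
    resp <- vapply(grid, function(v) {
      Xi <- Xs; Xi[, nm] <- v
      mean(predict(booster, Xi))
    }, 0)
    data.frame(value = as.numeric(grid), response = resp)
  })
  names(out) <- colnames(X)
  out
}

#' Predict occurrence probabilities for new covariate rows
#'
#' @param fit an \linkS4class{OccurrenceFit}.
#' @param newdata data.frame or matrix containing the training covariates.
#' @return probabilities clamped to [1e-6, 1 - 1e-12] (downstream log
#'   transforms require strictly positive exposure).
#' @export
predictOccurrence <- function(fit, newdata) {
  miss <- setdiff(fit@featureNames, colnames(newdata))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(as.data.frame(newdata)[, fit@featureNames, drop = FALSE])
  pmin(pmax(predict(fit@model, X), 1e-6), 1 - 1e-12)
}

#' Predict the occurrence (exposure) raster
#'
#' Applies the fitted submodel to every cell of the covariate stack,
#' producing the relative-likelihood-of-occurrence layer that is sampled
#' at segment midpoints as the exposure term.
#'
#' @param fit an \linkS4class{OccurrenceFit}.
#' @param rasters named list of \linkS4class{CovariateRaster} including
#'   every training covariate, on one common grid.
#' @return a \linkS4class{CovariateRaster} named "EGK" of cellwise
#'   probabilities in (0, 1).
#' @export
predictOccurrenceRaster <- function(fit, rasters) {
  miss <- setdiff(fit@featureNames, names(rasters))
  if (length(miss))
    stop("missing raster layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r1 <- rasters[[fit@featureNames[1L]]]
  X <- vapply(fit@featureNames,
              function(nm) as.vector(rasters[[nm]]@values),
              numeric(length(r1@values)))
  p <- predictOccurrence(fit, X)
  covariateRaster("EGK", matrix(p, nrow(r1@values), ncol(r1@values)),
                  origin = r1@origin, cellSize = r1@cellSize)
}
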