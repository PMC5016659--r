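#' Pipeline hyperparameters
#'
#' Collects the tunable settings of the end-to-end run. Defaults follow
#' the framework's standard configuration: background segments at twice
#' the collision count, a 300 m positional-accuracy cutoff, correlation
#' pruning at 0.75 (occurrence) and 0.7 (traffic), boosted-tree settings
#' of complexity 5 / learning rate 0.005, 500-tree forests, and the
#' exposure-volume-speed ANOVA term order.
#'
#' @param backgroundRatio background-to-collision segment ratio.
#' @param accuracyMax positional-accuracy cutoff in meters.
#' @param occCorThreshold,trafficCorThreshold correlation-prune thresholds.
#' @param treeComplexity,learningRate,maxTrees,nFolds boosted-tree settings.
#' @param nForestTrees random-forest size.
#' @param termOrder sequential-ANOVA term order for the structured model.
#' @param seed master seed for all pipeline randomness.
#' @return a named list of parameters.
#' @export
pipelineParams <- function(backgroundRatio = 2, accuracyMax = 300,
                           occCorThreshold = 0.75,
                           trafficCorThreshold = 0.7,
                           treeComplexity = 5L, learningRate = 0.005,
                           maxTrees = 3000L, nFolds = 10L,
                           nForestTrees = 500L,
                           termOrder = c("lnO", "lnV", "lnS"),
                           seed = 1L) {
  list(backgroundRatio = backgroundRatio, accuracyMax = accuracyMax,
       occCorThreshold = occCorThreshold,
       trafficCorThreshold = trafficCorThreshold,
       treeComplexity = treeComplexity, learningRate = learningRate,
       maxTrees = maxTrees, nFolds = nFolds,
       nForestTrees = nForestTrees, termOrder = termOrder,
       seed = as.integer(seed))
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  list(result = res, seconds = proc.time()[["elapsed"]] - t0)
}

#' Build the collision modeling dataset from records and predictions
#'
#' The dataset-construction contract: filter collision records by
#' positional accuracy, code their nearest segments 1, draw background
#' segments at the given ratio coded 0, sample the exposure raster at
#' segment midpoints, and attach the predicted volume and speed.
#'
#' @param records collision point records (columns x, y, accuracy).
#' @param segments segment set from \code{\link{splitRoadsByGrid}}.
#' @param egk exposure raster from \code{\link{predictOccurrenceRaster}}.
#' @param tvol,tspd per-segment predicted volume and speed, aligned with
#'   the segment table.
#' @param accuracyMax accuracy cutoff in meters (default 300).
#' @param backgroundRatio background-to-collision ratio (default 2).
#' @param seed seed for the background draw.
#' @return data.frame of \code{segment_id}, \code{O}, \code{V}, \code{S},
#'   \code{Y}.
#' @export
buildCollisionDataset <- function(records, segments, egk, tvol, tspd,
                                  accuracyMax = 300, backgroundRatio = 2,
                                  seed = 1L) {
  kept <- filterRecordsByAccuracy(records, accuracyMax)
  collIds <- assignRecordsToSegments(kept, segments)$collisionIds
  bgIds <- drawBackgroundSegments(segments, collIds,
                                  ratio = backgroundRatio, seed = seed)
  st <- segments$table
  ids <- c(collIds, bgIds)
  i <- match(ids, st$segment_id)
  data.frame(segment_id = ids,
             O = pmax(sampleRasterAtPoints(egk, st$mid_x[i], st$mid_y[i]),
                      1e-6),
             V = tvol[i], S = tspd[i],
             Y = rep(c(1L, 0L), c(length(collIds), length(bgIds))))
}

#' Validate a collision fit on hold-out records
#'
#' @param fit a \linkS4class{CollisionFit} (structured).
#' @param holdout data.frame with \code{O}, \code{V}, \code{S}, \code{Y}.
#' @return list with \code{auc} and a decile \code{calibration} table
#'   (mean predicted p, observed frequency, count, and 99\% binomial
#'   bounds).
#' @export
validateHoldout <- function(fit, holdout) {
  stopIfNot(nrow(holdout) > 0, "holdout set is empty")
  if (length(unique(holdout$Y)) < 2L)
    stop("ROC AUC undefined: holdout must contain both classes",
         call. = FALSE)
  p <- predictCollision(fit, holdout)
  auc <- rocAuc(p, holdout$Y)
  br <- unique(quantile(p, probs = seq(0, 1, 0.1)))
  bin <- cut(p, breaks = br, include.lowest = TRUE)
  calib <- do.call(rbind, lapply(split(seq_along(p), bin), function(idx) {
    n <- length(idx); ph <- mean(p[idx]); obs <- mean(holdout$Y[idx])
    ci <- stats::qbinom(c(0.005, 0.995), n, ph) / n
    data.frame(n = n, predicted = ph, observed = obs,
               lower99 = ci[1], upper99 = ci[2])
  }))
  rownames(calib) <- NULL
  list(auc = auc, calibration = calib)
}

#' Predict collision probabilities from a fitted collision model
#'
#' @param fit a \linkS4class{CollisionFit}.
#' @param newdata for the structured model, columns \code{O}, \code{V},
#'   \code{S}; for the alternative model, the raw covariate columns.
#' @return probabilities via the inverse cloglog link.
#' @export
predictCollision <- function(fit, newdata) {
  if (fit@kind == "structured") {
    newdata <- data.frame(lnO = log(pmax(newdata$O, 1e-6)),
                          lnV = log(newdata$V), lnS = log(newdata$S))
  }
  as.numeric(predict(fit@model, newdata = newdata, type = "response"))
}

#' Run the full collision-risk pipeline on a synthetic scene
#'
#' Executes every stage of the framework in order: exposure submodel
#' (correlation pruning, boosted-tree fit, prediction raster), both hazard
#' submodels (volume and speed forests, predictions on all segments),
#' collision-dataset construction (accuracy filter, nearest-segment
#' coding, background draw, midpoint sampling), the structured and
#' alternative cloglog GLMs on identical record sets, hold-out validation
#' on an independent batch of collision draws (new collision outcomes on
#' the same network, mirroring a temporally distinct validation year), and
#' the per-segment risk map.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param params settings from \code{\link{pipelineParams}}.
#' @param outputDir optional directory for the risk map and manifest.
#' @return a list with the fitted submodels (\code{occurrence},
#'   \code{volume}, \code{speed}), both collision fits
#'   (\code{collision}, \code{alternative}), \code{validation}
#'   (AUC + calibration), the per-segment \code{risk} table, and a
#'   \code{manifest} of metrics, seeds and timings.
#' @export
runPipeline <- function(scene, params = pipelineParams(),
                        outputDir = NULL) {
  manifest <- list(params = params,
                   version = as.character(utils::packageVersion("wvcrisk")),
                   stages = list(), outputs = character(0))
  st <- scene@segmentTable

  occ <- stage("occurrence", {
    tab <- buildOccurrenceTraining(scene@presences, scene@background,
                                   scene@rasters)
    pruned <- correlationPrune(tab, threshold = params$occCorThreshold)
    fit <- fitOccurrence(pruned$table,
                         treeComplexity = params$treeComplexity,
                         learningRate = params$learningRate,
                         nFolds = params$nFolds,
                         maxTrees = params$maxTrees,
                         seed = subSeed(params$seed, "occurrence"))
    list(fit = fit, dropped = pruned$dropped,
         raster = predictOccurrenceRaster(fit, scene@rasters))
  })
  manifest$stages$occurrence <- list(
    deviance_explained = occ$result$fit@devianceExplained,
    cv_auc = unname(occ$result$fit@cvAuc[1L]),
    cv_auc_sd = unname(occ$result$fit@cvAuc[2L]),
    n_trees = occ$result$fit@nTrees,
    dropped_covariates = occ$result$dropped,
    seconds = occ$seconds)

  traffic <- stage("traffic", {
    vol <- fitVolumeModel(scene@trafficObs,
                          corThreshold = params$trafficCorThreshold,
                          nTrees = params$nForestTrees,
                          seed = subSeed(params$seed, "volume"))
    spd <- fitSpeedModel(scene@trafficObs,
                         nTrees = params$nForestTrees,
                         seed = subSeed(params$seed, "speed"))
    list(volume = vol, speed = spd,
         tvol = predictTraffic(vol, st), tspd = predictTraffic(spd, st))
  })
  manifest$stages$traffic <- list(
    volume_pct_variance = traffic$result$volume@pctVarianceExplained,
    speed_pct_variance = traffic$result$speed@pctVarianceExplained,
    seconds = traffic$seconds)

  ds <- stage("collision-dataset", {
    buildCollisionDataset(scene@collisionRecords, scene@segments,
                          occ$result$raster, traffic$result$tvol,
                          traffic$result$tspd,
                          accuracyMax = params$accuracyMax,
                          backgroundRatio = params$backgroundRatio,
                          seed = subSeed(params$seed, "dataset"))
  })
  manifest$stages$dataset <- list(
    n_collision = sum(ds$result$Y), n_background = sum(ds$result$Y == 0L),
    seconds = ds$seconds)

  fits <- stage("collision-glm", {
    struct <- fitCollisionGlm(ds$result, termOrder = params$termOrder)
    i <- match(ds$result$segment_id, st$segment_id)
    raw <- cbind(ds$result["Y"],
                 covariateTableAt(scene, st$mid_x[i], st$mid_y[i]),
                 st[i, c("RDCLASS", "KMTODEV", "KMTOHWY", "POPDENS",
                         "RDDENS")])
    alt <- fitAlternativeGlm(raw, setdiff(names(raw), "Y"))
    list(structured = struct, alternative = alt)
  })
  manifest$stages$collision <- list(
    deviance_explained = fits$result$structured@devianceExplained,
    aic = fits$result$structured@aic,
    coefficients = as.list(fits$result$structured@coefficients[, "Estimate"]),
    anova_shares = as.list(fits$result$structured@anova),
    alternative_deviance_explained =
      fits$result$alternative@devianceExplained,
    alternative_aic = fits$result$alternative@aic,
    seconds = fits$seconds)

  val <- stage("validation", {
    holdoutSeed <- subSeed(params$seed, "holdout-batch")
    sim <- simulateCollisions(st$O, st$V, st$S, scene@truth@riskCoefs,
                              seed = holdoutSeed,
                              segmentId = st$segment_id)
    hit <- st[sim$Y == 1L, , drop = FALSE]
    recs <- collisionRecordsFromSegments(hit, scene@config, 50,
                                         stream = "holdout-records")
    hold <- buildCollisionDataset(recs, scene@segments,
                                  occ$result$raster, traffic$result$tvol,
                                  traffic$result$tspd,
                                  accuracyMax = params$accuracyMax,
                                  backgroundRatio = params$backgroundRatio,
                                  seed = holdoutSeed)
    validateHoldout(fits$result$structured, hold)
  })
  manifest$stages$validation <- list(auc = val$result$auc,
                                     seconds = val$seconds)

  risk <- stage("risk-map", {
    i <- seq_len(nrow(st))
    rk <- data.frame(
      segment_id = st$segment_id,
      O = pmax(sampleRasterAtPoints(occ$result$raster, st$mid_x, st$mid_y),
               1e-6),
      V = traffic$result$tvol, S = traffic$result$tspd)
    rk$prob <- predictCollision(fits$result$structured, rk)
    rk
  })
  manifest$stages$risk_map <- list(n_segments = nrow(risk$result),
                                   mean_prob = mean(risk$result$prob),
                                   seconds = risk$seconds)

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    paths <- exportRiskMap(scene@segments, risk$result,
                           file.path(outputDir, "risk_map.geojson"),
                           file.path(outputDir, "risk_map.csv"))
    manifest$outputs <- unlist(paths, use.names = FALSE)
    jsonlite::write_json(manifestWithoutTiming(manifest),
                         file.path(outputDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs <- c(manifest$outputs,
                          file.path(outputDir, "run_manifest.json"))
  }

  list(occurrence = occ$result$fit, exposureRaster = occ$result$raster,
       volume = traffic$result$volume, speed = traffic$result$speed,
       dataset = ds$result,
       collision = fits$result$structured,
       alternative = fits$result$alternative,
       validation = val$result, risk = risk$result,
       manifest = manifest)
}

#' @rdname runPipeline
#' @param manifest a manifest from \code{runPipeline}.
#' @return \code{manifestWithoutTiming} strips wall-clock entries so two
#'   runs of the same configuration compare identical.
#' @export
manifestWithoutTiming <- function(manifest) {
  manifest$stages <- lapply(manifest$stages, function(s) {
    s$seconds <- NULL
    s
  })
  manifest
}

# Raw covariate values (habitat layers) at points, for the alternative
# flat model.
covariateTableAt <- function(scene, x, y) {
  out <- lapply(scene@rasters, function(r) sampleRasterAtPoints(r, x, y))
  as.data.frame(out)
}
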