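#' Configuration of a synthetic study area
#'
#' Describes the landscape and road network to simulate: a rectangular
#' extent gridded at \code{cellSize} (default 1 km, the resolution of the
#' analysis grid), a set of named spatially autocorrelated covariate
#' rasters, and a road network with a given class mix.
#'
#' @slot extent numeric(4) c(xmin, xmax, ymin, ymax) in projected meters.
#' @slot cellSize grid resolution in meters (default 1000).
#' @slot covariateNames names of the environmental covariate layers.
#' @slot smoothingScale autocorrelation length of the covariate fields, in
#'   cells (Gaussian kernel sd); 0 gives white noise.
#' @slot nRoads number of road polylines.
#' @slot roadClassMix named proportions over the six road classes, sum 1.
#' @slot seed master seed; all substreams derive from it.
#' @export
setClass("SceneConfig",
  representation(extent = "numeric", cellSize = "numeric",
                 covariateNames = "character", smoothingScale = "numeric",
                 nRoads = "integer", roadClassMix = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msgs <- character()
    e <- object@extent
    if (length(e) != 4L || e[2] <= e[1] || e[4] <= e[3])
      msgs <- c(msgs, "extent must enclose a strictly positive area")
    if (object@cellSize <= 0) msgs <- c(msgs, "cellSize must be positive")
    if (object@smoothingScale < 0)
      msgs <- c(msgs, "smoothingScale must be nonnegative")
    if (object@nRoads < 1L) msgs <- c(msgs, "nRoads must be at least 1")
    mix <- object@roadClassMix
    if (!setequal(names(mix), roadClasses()))
      msgs <- c(msgs, "roadClassMix must name all six road classes")
    if (abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
      msgs <- c(msgs, "roadClassMix proportions must be nonnegative and sum to 1")
    if (length(msgs)) msgs else TRUE
  })

#' @rdname SceneConfig-class
#' @param extent numeric(4) c(xmin, xmax, ymin, ymax) in meters.
#' @param cellSize grid resolution in meters.
#' @param covariateNames covariate layer names.
#' @param smoothingScale covariate autocorrelation length in cells.
#' @param nRoads number of roads.
#' @param roadClassMix named proportions over \code{\link{roadClasses}()}.
#' @param seed integer master seed.
#' @export
sceneConfig <- function(extent = c(0, 40000, 0, 40000), cellSize = 1000,
                        covariateNames = c("ELEV", "GREEN", "PRECDM",
                                           "TREEDENS"),
                        smoothingScale = 3, nRoads = 60L,
                        roadClassMix = c(freeway = 0.05, highway = 0.10,
                                         arterial = 0.15, subarterial = 0.15,
                                         collector = 0.20, local = 0.35),
                        seed = 1L) {
  new("SceneConfig", extent = as.numeric(extent),
      cellSize = as.numeric(cellSize),
      covariateNames = as.character(covariateNames),
      smoothingScale = as.numeric(smoothingScale),
      nRoads = as.integer(nRoads), roadClassMix = roadClassMix,
      seed = as.integer(seed))
}

setMethod("show", "SceneConfig", function(object) {
  e <- object@extent
  cat(sprintf(
    "SceneConfig: %.0f x %.0f km extent, %g m cells, %d covariates, %d roads, seed %d\n",
    (e[2] - e[1]) / 1000, (e[4] - e[3]) / 1000, object@cellSize,
    length(object@covariateNames), object@nRoads, object@seed))
})

#' @rdname SceneConfig-class
#' @param config a \code{SceneConfig}.
#' @return \code{sceneGrid} returns the \linkS4class{GridSpec} tiling the
#'   extent.
#' @export
sceneGrid <- function(config) {
  e <- config@extent
  gridSpec(origin = c(e[1], e[3]), cellSize = config@cellSize,
           nCols = ceiling((e[2] - e[1]) / config@cellSize),
           nRows = ceiling((e[4] - e[3]) / config@cellSize))
}

#' Ground-truth parameters of a synthetic scene
#'
#' The known data-generating process every downstream model tries to
#' recover: a logistic occurrence surface over the covariates, a log-normal
#' traffic-volume model driven by road class and proximity predictors,
#' class-dependent posted speeds, and the collision-rate coefficients.
#'
#' @slot occCoefs named coefficients ("(Intercept)" plus covariate names)
#'   of the true occurrence probability on the logistic scale.
#' @slot volCoefs named coefficients of true ln(AADT) on "(Intercept)",
#'   "RDCLASS" (ordered intensity 1-6), "KMTODEV", "KMTOHWY" (km),
#'   "POPDENS" (persons/km^2), "RDDENS" (km/km^2).
#' @slot volSigma log-scale noise sd of AADT (>= 0).
#' @slot speedByClass named mean posted speed (km/h) per road class.
#' @slot riskCoefs a \linkS4class{RiskCoefficients}.
#' @export
setClass("TruthParameters",
  representation(occCoefs = "numeric", volCoefs = "numeric",
                 volSigma = "numeric", speedByClass = "numeric",
                 riskCoefs = "RiskCoefficients"),
  validity = function(object) {
    msgs <- character()
    if (object@volSigma < 0) msgs <- c(msgs, "volSigma must be >= 0")
    if (!setequal(names(object@speedByClass), roadClasses()) ||
        any(object@speedByClass <= 0))
      msgs <- c(msgs, "speedByClass must give a positive mean for each class")
    if (!"(Intercept)" %in% names(object@occCoefs))
      msgs <- c(msgs, "occCoefs must include an (Intercept)")
    if (length(msgs)) msgs else TRUE
  })

#' @rdname TruthParameters-class
#' @param occCoefs,volCoefs,volSigma,speedByClass,riskCoefs see slots.
#' @export
truthParameters <- function(occCoefs, volCoefs, volSigma = 0.3,
                            speedByClass = c(freeway = 100, highway = 90,
                                             arterial = 80, subarterial = 70,
                                             collector = 60, local = 50),
                            riskCoefs = riskCoefficients(-11, 1, 1, 1)) {
  new("TruthParameters", occCoefs = occCoefs, volCoefs = volCoefs,
      volSigma = as.numeric(volSigma), speedByClass = speedByClass,
      riskCoefs = riskCoefs)
}

#' @rdname TruthParameters-class
#' @param config a \linkS4class{SceneConfig}; the default truth gives the
#'   first covariates strong, sign-alternating effects on occurrence, a
#'   volume model dominated by road class, and unit risk slopes.
#' @export
defaultTruth <- function(config) {
  nms <- config@covariateNames
  base <- c(1.6, -1.1, 0.8, -0.5, 0.4, -0.3)
  occ <- c(-1, rep_len(base, length(nms)))
  names(occ) <- c("(Intercept)", nms)
  truthParameters(
    occCoefs = occ,
    volCoefs = c("(Intercept)" = 4.2, RDCLASS = 0.8, KMTODEV = -0.05,
                 KMTOHWY = -0.03, POPDENS = 0.002, RDDENS = 0.05),
    volSigma = 0.3)
}

setMethod("show", "TruthParameters", function(object) {
  cat("TruthParameters\n  occurrence (logit):",
      paste(sprintf("%s=%.2g", names(object@occCoefs), object@occCoefs),
            collapse = ", "),
      "\n  ln(AADT):",
      paste(sprintf("%s=%.2g", names(object@volCoefs), object@volCoefs),
            collapse = ", "),
      sprintf("(sigma %.2g)", object@volSigma), "\n  ")
  show(object@riskCoefs)
})

#' Generate spatially autocorrelated covariate rasters
#'
#' One raster per configured covariate name: Gaussian white noise smoothed
#' with a separable Gaussian kernel of sd \code{smoothingScale} cells, then
#' standardized to mean 0 and sd 1 across cells. \code{smoothingScale = 0}
#' yields standardized white noise. Reproducible from the config seed.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return named list of \linkS4class{CovariateRaster} objects.
#' @export
generateCovariateRasters <- function(config) {
  validObject(config)
  grid <- sceneGrid(config)
  nr <- grid@nRows; nc <- grid@nCols
  out <- lapply(config@covariateNames, function(nm) {
    z <- withSubSeed(config@seed, paste0("raster-", nm),
                     matrix(rnorm(nr * nc), nr, nc))
    if (config@smoothingScale > 0) {
      z <- smoothMatrix(z, config@smoothingScale)
    }
    z <- (z - mean(z)) / sd(z)
    covariateRaster(nm, z, origin = grid@origin, cellSize = grid@cellSize)
  })
  names(out) <- config@covariateNames
  out
}

# Separable Gaussian smoothing with kernel rows renormalized at the edges.
smoothMatrix <- function(z, scale) {
  k <- smootherMatrix(nrow(z), scale)
  k2 <- smootherMatrix(ncol(z), scale)
  k %*% z %*% t(k2)
}

smootherMatrix <- function(n, scale) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * scale^2)))
  K[abs(row(K) - col(K)) > ceiling(4 * scale)] <- 0
  K / rowSums(K)
}

#' Generate a synthetic road network
#'
#' Roads are correlated random walks: a random start, heading and step
#' count, with heading jitter between steps; walks are truncated at the
#' extent boundary so the network stays inside the scene. Classes are drawn
#' from the configured mix.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return a \linkS4class{RoadNetwork}.
#' @export
generateRoadNetwork <- function(config) {
  validObject(config)
  e <- config@extent
  diag <- sqrt((e[2] - e[1])^2 + (e[4] - e[3])^2)
  withSubSeed(config@seed, "roads", {
    classes <- sample(names(config@roadClassMix), config@nRoads,
                      replace = TRUE, prob = config@roadClassMix)
    coords <- lapply(seq_len(config@nRoads), function(i) {
      start <- c(runif(1, e[1], e[2]), runif(1, e[3], e[4]))
      heading <- runif(1, 0, 2 * pi)
      nStep <- sample(4:7, 1L)
      step <- runif(1, 0.08, 0.18) * diag
      pts <- matrix(NA_real_, nStep + 1L, 2L)
      pts[1L, ] <- start
      for (k in seq_len(nStep)) {
        heading <- heading + rnorm(1, 0, 0.25)
        nxt <- pts[k, ] + step * c(cos(heading), sin(heading))
        # truncate the step at the extent boundary
        t <- 1
        if (nxt[1] < e[1]) t <- min(t, (e[1] - pts[k, 1]) / (nxt[1] - pts[k, 1]))
        if (nxt[1] > e[2]) t <- min(t, (e[2] - pts[k, 1]) / (nxt[1] - pts[k, 1]))
        if (nxt[2] < e[3]) t <- min(t, (e[3] - pts[k, 2]) / (nxt[2] - pts[k, 2]))
        if (nxt[2] > e[4]) t <- min(t, (e[4] - pts[k, 2]) / (nxt[2] - pts[k, 2]))
        if (t < 1) {
          pts[k + 1L, ] <- pts[k, ] + 0.999 * t * step *
            c(cos(heading), sin(heading))
          return(pts[seq_len(k + 1L), , drop = FALSE])
        }
        pts[k + 1L, ] <- nxt
      }
      pts
    })
    keep <- vapply(coords, function(m) nrow(m) >= 2L &&
                     polylineLength(m) > 0, TRUE)
    roadNetwork(coords[keep], classes[keep])
  })
}

#' Generate presence and background point sets
#'
#' Background points are uniform over the raster extent. Presence points
#' are drawn from the true occurrence surface
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \beta \cdot \mathrm{covariates})}:
#' a cell is selected with probability proportional to its occurrence
#' probability and the point placed uniformly within it (exactly the
#' rejection-sampling distribution against the cellwise-constant surface).
#' An optional road-proximity bias multiplies cell weights by
#' \eqn{1 + b\,e^{-d/s}} with \eqn{d} the cell-center distance to the
#' nearest road, emulating survey records concentrated near roads.
#'
#' @param rasters named list of \linkS4class{CovariateRaster}.
#' @param truth a \linkS4class{TruthParameters}.
#' @param nPresence,nBackground point counts (background convention:
#'   10,000).
#' @param seed integer seed.
#' @param roadBias optional list(network, strength = b, scale = s meters).
#' @return list of data.frames \code{presences} and \code{background},
#'   each with columns \code{x}, \code{y}.
#' @export
generateSpeciesData <- function(rasters, truth, nPresence, nBackground,
                                seed = 1L, roadBias = NULL) {
  nms <- setdiff(names(truth@occCoefs), "(Intercept)")
  stopIfNot(all(nms %in% names(rasters)),
            "occCoefs dimension must match the covariate rasters")
  p <- trueOccurrenceMatrix(rasters, truth)
  r1 <- rasters[[1L]]
  w <- as.vector(p)
  if (!is.null(roadBias)) {
    grid <- gridSpec(r1@origin, r1@cellSize, ncol(p), nrow(p))
    ctr <- cellCenters(grid)
    d <- rep(Inf, nrow(ctr))
    for (m in roadBias$network@coords)
      d <- pmin(d, pointsToPolylineDistance(ctr[, 1], ctr[, 2], m))
    # cellCenters runs column-fastest (row-major); matrix() fills
    # column-major, so fill by row to align with p
    dMat <- matrix(d, nrow(p), ncol(p), byrow = TRUE)
    w <- w * (1 + roadBias$strength * exp(-as.vector(dMat) / roadBias$scale))
  }
  e <- rasterExtent(r1)
  withSubSeed(seed, "species-points", {
    bg <- data.frame(x = runif(nBackground, e[1], e[2]),
                     y = runif(nBackground, e[3], e[4]))
    if (nPresence == 0L) {
      pres <- data.frame(x = numeric(0), y = numeric(0))
    } else {
      cells <- sample.int(length(w), nPresence, replace = TRUE, prob = w)
      row <- (cells - 1L) %% nrow(p) + 1L
      col <- (cells - 1L) %/% nrow(p) + 1L
      pres <- data.frame(
        x = r1@origin[1] + (col - 1L + runif(nPresence)) * r1@cellSize,
        y = r1@origin[2] + (row - 1L + runif(nPresence)) * r1@cellSize)
    }
    list(presences = pres, background = bg)
  })
}

# True occurrence probability per cell (matrix aligned with the rasters).
trueOccurrenceMatrix <- function(rasters, truth) {
  co <- truth@occCoefs
  eta <- matrix(co[["(Intercept)"]],
                nrow(rasters[[1L]]@values), ncol(rasters[[1L]]@values))
  for (nm in setdiff(names(co), "(Intercept)"))
    eta <- eta + co[[nm]] * rasters[[nm]]@values
  plogis(eta)
}

cellCenters <- function(grid) {
  xs <- grid@origin[1] + (seq_len(grid@nCols) - 0.5) * grid@cellSize
  ys <- grid@origin[2] + (seq_len(grid@nRows) - 0.5) * grid@cellSize
  cbind(x = rep(xs, times = grid@nRows), y = rep(ys, each = grid@nCols))
}

#' A complete synthetic scene with known ground truth
#'
#' Bundles everything a study area provides — covariate rasters, the road
#' network and its grid segmentation, species presence/background points,
#' traffic observations on a subset of segments, per-segment true exposure
#' and hazard with simulated collision outcomes, and point-format collision
#' records (jittered midpoints with a positional-accuracy attribute) — plus
#' the generating truth.
#'
#' @slot config the \linkS4class{SceneConfig}.
#' @slot truth the \linkS4class{TruthParameters}.
#' @slot rasters named list of covariate rasters.
#' @slot popdens population-density raster (persons/km^2), a hazard-side
#'   predictor field kept separate from the habitat covariates.
#' @slot network the \linkS4class{RoadNetwork}.
#' @slot segments grid segmentation (list: table, geometry).
#' @slot presences,background species point sets.
#' @slot trafficObs observed AADT and speed on a subset of segments.
#' @slot segmentTable per-segment predictors, true O/V/S, rate, prob, Y.
#' @slot collisionRecords point records with accuracy, derived from
#'   collision segments.
#' @slot devCenters development-center coordinates (drives KMTODEV).
#' @export
setClass("SyntheticScene",
  representation(config = "SceneConfig", truth = "TruthParameters",
                 rasters = "list", popdens = "CovariateRaster",
                 network = "RoadNetwork", segments = "list",
                 presences = "data.frame", background = "data.frame",
                 trafficObs = "data.frame", segmentTable = "data.frame",
                 collisionRecords = "data.frame", devCenters = "matrix"),
  validity = function(object) {
    st <- object@segmentTable
    if (nrow(st) && !all(st$segment_id %in% object@segments$table$segment_id))
      return("every collision outcome must attach to an existing segment")
    e <- object@config@extent
    pr <- object@presences
    if (nrow(pr) && (any(pr$x < e[1] | pr$x > e[2]) ||
                     any(pr$y < e[3] | pr$y > e[4])))
      return("presences must fall inside the extent")
    TRUE
  })

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d cells, %d segments (%d collision-coded), %d presences, %d background, %d traffic obs\n",
    prod(dim(object@rasters[[1L]]@values)), nrow(object@segmentTable),
    sum(object@segmentTable$Y), nrow(object@presences),
    nrow(object@background), nrow(object@trafficObs)))
})

#' @rdname SyntheticScene-class
#' @param scene a \code{SyntheticScene}.
#' @export
sceneSegments <- function(scene) scene@segments

#' @rdname SyntheticScene-class
#' @export
sceneTruth <- function(scene) scene@truth

#' @rdname SyntheticScene-class
#' @export
segmentTable <- function(scene) scene@segmentTable

#' Generate a full synthetic scene
#'
#' Runs the whole data-generating process in order: covariate rasters, a
#' population-density field, the road network and its grid segmentation,
#' per-segment predictors (RDCLASS intensity, distances to development and
#' to major roads, population density, road density), true occurrence /
#' volume / speed, simulated collision outcomes, species points, traffic
#' observations, and point-format collision records. Every random draw
#' flows from \code{config@seed} through independent named substreams, so
#' the scene is a pure function of (config, truth).
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param truth a \linkS4class{TruthParameters}; default
#'   \code{defaultTruth(config)}.
#' @param nPresence,nBackground species point counts.
#' @param trafficObsFraction fraction of segments carrying observed AADT
#'   and speed (default 0.5, emulating counts available on major roads
#'   only).
#' @param nDevCenters number of development (urban) centers.
#' @param recordJitterSd sd (m) of the positional jitter applied to
#'   collision records around segment midpoints.
#' @return a \linkS4class{SyntheticScene}.
#' @export
generateScene <- function(config, truth = defaultTruth(config),
                          nPresence = 500L, nBackground = 2000L,
                          trafficObsFraction = 0.5, nDevCenters = 3L,
                          recordJitterSd = 50) {
  validObject(config); validObject(truth)
  grid <- sceneGrid(config)
  rasters <- generateCovariateRasters(config)
  # population density: its own smoothed field, scaled to 0..500 people/km^2
  pdZ <- withSubSeed(config@seed, "raster-POPDENS",
                     matrix(rnorm(grid@nRows * grid@nCols),
                            grid@nRows, grid@nCols))
  pdZ <- smoothMatrix(pdZ, max(config@smoothingScale, 1))
  pdZ <- 500 * plogis(2 * (pdZ - mean(pdZ)) / sd(pdZ))
  popdens <- covariateRaster("POPDENS", pdZ, grid@origin, grid@cellSize)
  network <- generateRoadNetwork(config)
  segments <- splitRoadsByGrid(network, grid)
  st <- segments$table
  e <- config@extent
  dev <- withSubSeed(config@seed, "dev-centers",
                     cbind(runif(nDevCenters, e[1], e[2]),
                           runif(nDevCenters, e[3], e[4])))
  st$RDCLASS <- roadClassIntensity(st$road_class)
  st$KMTODEV <- distanceToPoints(st$mid_x, st$mid_y, dev) / 1000
  major <- which(st$road_class %in% c("freeway", "highway"))
  st$KMTOHWY <- if (length(major)) {
    d <- rep(Inf, nrow(st))
    for (i in major)
      d <- pmin(d, pointsToPolylineDistance(st$mid_x, st$mid_y,
                                            segments$geometry[[i]]))
    d / 1000
  } else rep(sqrt((e[2] - e[1])^2 + (e[4] - e[3])^2) / 1000, nrow(st))
  st$POPDENS <- sampleRasterAtPoints(popdens, st$mid_x, st$mid_y)
  rdd <- aggregate(st$length, list(cell_id = st$cell_id), sum)
  st$RDDENS <- rdd$x[match(st$cell_id, rdd$cell_id)] / 1000
  # true exposure and hazard
  occP <- trueOccurrenceMatrix(rasters, truth)
  occR <- covariateRaster("trueO", occP, grid@origin, grid@cellSize)
  st$O <- pmax(sampleRasterAtPoints(occR, st$mid_x, st$mid_y), 1e-6)
  vc <- truth@volCoefs
  lnV <- vc[["(Intercept)"]] + vc[["RDCLASS"]] * st$RDCLASS +
    vc[["KMTODEV"]] * st$KMTODEV + vc[["KMTOHWY"]] * st$KMTOHWY +
    vc[["POPDENS"]] * st$POPDENS + vc[["RDDENS"]] * st$RDDENS
  st$V <- withSubSeed(config@seed, "traffic-volume",
                      exp(lnV + rnorm(nrow(st), 0, truth@volSigma)))
  st$S <- withSubSeed(config@seed, "traffic-speed", {
    s <- truth@speedByClass[st$road_class] + rnorm(nrow(st), 0, 4)
    pmax(5 * round(s / 5), 30)
  })
  sim <- simulateCollisions(st$O, st$V, st$S, truth@riskCoefs,
                            seed = subSeed(config@seed, "collisions"),
                            segmentId = st$segment_id)
  st$rate <- sim$rate; st$prob <- sim$prob; st$Y <- sim$Y
  pts <- generateSpeciesData(rasters, truth, nPresence, nBackground,
                             seed = subSeed(config@seed, "species"))
  obsIdx <- withSubSeed(config@seed, "traffic-obs",
                        sort(sample(nrow(st),
                                    max(1L, round(trafficObsFraction *
                                                  nrow(st))))))
  trafficObs <- st[obsIdx, c("segment_id", "RDCLASS", "KMTODEV", "KMTOHWY",
                             "POPDENS", "RDDENS")]
  trafficObs$AADT <- st$V[obsIdx]
  trafficObs$SPEEDLMT <- st$S[obsIdx]
  rownames(trafficObs) <- NULL
  recs <- collisionRecordsFromSegments(st, config, recordJitterSd)
  new("SyntheticScene", config = config, truth = truth, rasters = rasters,
      popdens = popdens, network = network, segments = segments,
      presences = pts$presences, background = pts$background,
      trafficObs = trafficObs, segmentTable = st,
      collisionRecords = recs, devCenters = dev)
}

distanceToPoints <- function(x, y, pts) {
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(pts)))
    d <- pmin(d, sqrt((x - pts[i, 1])^2 + (y - pts[i, 2])^2))
  d
}

# Point-format collision reports: jittered segment midpoints with a
# positional-accuracy attribute. A minority of records carry accuracy
# worse than 300 m so the accuracy filter has work to do.
collisionRecordsFromSegments <- function(st, config, jitterSd,
                                         stream = "collision-records") {
  hit <- st[st$Y == 1L, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      timestamp = character(0), accuracy = numeric(0),
                      source_id = character(0), stringsAsFactors = FALSE))
  }
  e <- config@extent
  withSubSeed(config@seed, stream, {
    n <- nrow(hit)
    coarse <- runif(n) < 0.15
    acc <- ifelse(coarse, runif(n, 301, 800), runif(n, 10, 300))
    data.frame(
      x = pmin(pmax(hit$mid_x + rnorm(n, 0, jitterSd), e[1]), e[2]),
      y = pmin(pmax(hit$mid_y + rnorm(n, 0, jitterSd), e[3]), e[4]),
      timestamp = sprintf("2012-%02d-%02d", sample(12, n, TRUE),
                          sample(28, n, TRUE)),
      accuracy = acc,
      source_id = sprintf("SYN-%05d", hit$segment_id),
      stringsAsFactors = FALSE)
  })
}
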