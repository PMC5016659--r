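# Shared fixture builders. Everything is generated in code at test time.

smallConfig <- function(seed = 11L, ...) {
  sceneConfig(extent = c(0, 20000, 0, 20000), cellSize = 1000,
              covariateNames = c("ELEV", "GREEN", "PRECDM"),
              smoothingScale = 3, nRoads = 25L, seed = seed, ...)
}

# Cached default small scene (built once per test run).
.fixtures <- new.env(parent = emptyenv())
smallScene <- function() {
  if (is.null(.fixtures$scene))
    .fixtures$scene <- generateScene(smallConfig())
  .fixtures$scene
}

# Memoized default pipeline run on the small scene.
pipelineFixture <- function() {
  if (is.null(.fixtures$pipe)) {
    .fixtures$pipe <- runPipeline(smallScene(),
                                  pipelineParams(maxTrees = 1200L,
                                                 nFolds = 5L, seed = 2L))
  }
  .fixtures$pipe
}

# Memoized strong-signal occurrence fit on a two-covariate landscape.
occFixture <- function() {
  if (is.null(.fixtures$occ)) {
    cfg <- sceneConfig(extent = c(0, 30000, 0, 30000),
                       covariateNames = c("ELEV", "GREEN"),
                       smoothingScale = 2, nRoads = 10L, seed = 51L)
    rasters <- generateCovariateRasters(cfg)
    # a rare species with strong habitat preference: highly discriminable
    truth <- truthParameters(
      occCoefs = c("(Intercept)" = -4, ELEV = 3, GREEN = -2.5),
      volCoefs = c("(Intercept)" = 4, RDCLASS = 0.8, KMTODEV = 0,
                   KMTOHWY = 0, POPDENS = 0, RDDENS = 0))
    pts <- generateSpeciesData(rasters, truth, 800L, 2500L, seed = 5L)
    train <- buildOccurrenceTraining(pts$presences, pts$background, rasters)
    fit <- fitOccurrence(train, maxTrees = 1500L, nFolds = 5L, seed = 6L)
    .fixtures$occ <- list(fit = fit, rasters = rasters, train = train)
  }
  .fixtures$occ
}

# A straight horizontal 2-vertex road.
straightRoad <- function(x0, y0, x1, y1, class = "local") {
  roadNetwork(list(rbind(c(x0, y0), c(x1, y1))), class)
}

# Random small network inside a grid, for property-style loops.
randomNetwork <- function(grid, nRoads = 5L) {
  e <- gridExtent(grid)
  coords <- lapply(seq_len(nRoads), function(i) {
    n <- sample(2:5, 1L)
    cbind(runif(n, e[1], e[2]), runif(n, e[3], e[4]))
  })
  roadNetwork(coords, sample(roadClasses(), nRoads, replace = TRUE))
}

# Brute-force clip of a single line segment against one cell rectangle
# (Liang-Barsky), used as the segmentation oracle.
clipSegmentToRect <- function(p, q, xmin, xmax, ymin, ymax) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (side in 1:4) {
    pp <- c(-d[1], d[1], -d[2], d[2])[side]
    qq <- c(p[1] - xmin, xmax - p[1], p[2] - ymin, ymax - p[2])[side]
    if (pp == 0) {
      if (qq < 0) return(0)
    } else {
      r <- qq / pp
      if (pp < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 >= t1) return(0)
  (t1 - t0) * sqrt(sum(d^2))
}

# Oracle: total clipped length of a polyline inside every grid cell.
oracleCellLengths <- function(m, grid) {
  out <- numeric(grid@nCols * grid@nRows)
  for (r in seq_len(grid@nRows)) {
    for (cc in seq_len(grid@nCols)) {
      xmin <- grid@origin[1] + (cc - 1) * grid@cellSize
      ymin <- grid@origin[2] + (r - 1) * grid@cellSize
      len <- 0
      for (k in seq_len(nrow(m) - 1L)) {
        len <- len + clipSegmentToRect(m[k, ], m[k + 1L, ],
                                       xmin, xmin + grid@cellSize,
                                       ymin, ymin + grid@cellSize)
      }
      out[(r - 1L) * grid@nCols + cc] <- len
    }
  }
  out
}

# Two-sample-free two-dimensional Kolmogorov-Smirnov test against the
# uniform distribution on a rectangle (Peacock statistic over the four
# quadrant orientations, asymptotic p per Press et al.).
ks2dUniform <- function(x, y, ext) {
  u <- (x - ext[1]) / (ext[2] - ext[1])
  v <- (y - ext[3]) / (ext[4] - ext[3])
  n <- length(u)
  d <- 0
  for (i in seq_len(n)) {
    fu <- u <= u[i]; fv <- v <= v[i]
    emp <- c(mean(fu & fv), mean(fu & !fv), mean(!fu & fv), mean(!fu & !fv))
    thr <- c(u[i] * v[i], u[i] * (1 - v[i]), (1 - u[i]) * v[i],
             (1 - u[i]) * (1 - v[i]))
    d <- max(d, abs(emp - thr))
  }
  r2 <- stats::cor(u, v)^2
  lambda <- sqrt(n) * d / (1 + sqrt(1 - r2) * (0.25 - 0.75 / sqrt(n)))
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(statistic = d, p.value = max(min(p, 1), 0))
}

# Direct log-likelihood maximization oracle for the cloglog binomial GLM
# (BFGS on the analytic negative log-likelihood and gradient).
cloglogMleOracle <- function(X, y, start = rep(0, ncol(X))) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    p <- pmin(pmax(-expm1(-exp(eta)), 1e-14), 1 - 1e-14)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  gr <- function(b) {
    eta <- as.numeric(X %*% b)
    p <- pmin(pmax(-expm1(-exp(eta)), 1e-14), 1 - 1e-14)
    dpdeta <- exp(eta - exp(eta))
    w <- (y / p - (1 - y) / (1 - p)) * dpdeta
    -as.numeric(crossprod(X, w))
  }
  fit <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  stats::optim(fit$par, nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

# Log-uniform draws used by the recovery simulations.
rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# Intercept placing the mean log-rate of simulateRecords() at `target`
# (so outcomes mix both classes) given the slopes; the means are those of
# the log-uniform O, V, S ranges used by simulateRecords().
calibratedBeta0 <- function(b1, b2, b3, target = -1.5) {
  target - (b1 * mean(log(c(0.02, 1))) + b2 * mean(log(c(100, 20000))) +
              b3 * mean(log(c(40, 110))))
}

# Segment records with independent log-uniform O, V, S and outcomes from
# the encounter model.
simulateRecords <- function(n, coefs, seed) {
  withr::with_seed(seed, {
    O <- rlogunif(n, 0.02, 1)
    V <- rlogunif(n, 100, 20000)
    S <- rlogunif(n, 40, 110)
    sim <- simulateCollisions(O, V, S, coefs, seed = seed)
    data.frame(segment_id = seq_len(n), O = O, V = V, S = S,
               Y = sim$Y, prob = sim$prob)
  })
}
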