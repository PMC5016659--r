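test_that("species generator honors counts and the flat-truth case", {
  cfg <- smallConfig(seed = 21L)
  rasters <- generateCovariateRasters(cfg)
  flat <- truthParameters(
    occCoefs = c("(Intercept)" = 0, ELEV = 0, GREEN = 0, PRECDM = 0),
    volCoefs = c("(Intercept)" = 4, RDCLASS = 0.8, KMTODEV = 0,
                 KMTOHWY = 0, POPDENS = 0, RDDENS = 0))
  pts <- generateSpeciesData(rasters, flat, nPresence = 2000L,
                             nBackground = 10000L, seed = 3L)
  expect_equal(nrow(pts$background), 10000L)
  expect_equal(nrow(pts$presences), 2000L)
  # flat truth surface: presences indistinguishable from uniform
  ks <- ks2dUniform(pts$presences$x, pts$presences$y, cfg@extent)
  expect_gt(ks$p.value, 0.01)
  # zero presences allowed
  none <- generateSpeciesData(rasters, flat, 0L, 100L, seed = 3L)
  expect_equal(nrow(none$presences), 0L)
})

test_that("presences concentrate where a strong covariate says they should", {
  cfg <- smallConfig(seed = 22L)
  rasters <- generateCovariateRasters(cfg)
  truth <- truthParameters(
    occCoefs = c("(Intercept)" = -1, ELEV = 3, GREEN = 0, PRECDM = 0),
    volCoefs = c("(Intercept)" = 4, RDCLASS = 0.8, KMTODEV = 0,
                 KMTOHWY = 0, POPDENS = 0, RDDENS = 0))
  pts <- generateSpeciesData(rasters, truth, 1500L, 1500L, seed = 4L)
  atP <- sampleRasterAtPoints(rasters$ELEV, pts$presences$x, pts$presences$y)
  atB <- sampleRasterAtPoints(rasters$ELEV, pts$background$x,
                              pts$background$y)
  expect_gt(mean(atP), mean(atB))
})

test_that("collision simulator follows the Poisson encounter mapping", {
  # effectively zero rate: all outcomes zero with probability zero
  off <- simulateCollisions(0.5, 1000, 60, riskCoefficients(-1e6), seed = 1L)
  expect_equal(off$prob, 0)
  expect_equal(off$Y, 0L)
  # unit rate is analytically forced
  unit <- simulateCollisions(1, 1, 1, riskCoefficients(0, 1, 1, 1), seed = 1L)
  expect_equal(unit$prob, 0.6321205588285577, tolerance = 1e-12)
  # domain errors name the offending segment
  expect_error(simulateCollisions(0.5, c(100, -5), 60,
                                  riskCoefficients(-10), seed = 1L,
                                  segmentId = c(7L, 9L)),
               "traffic volume V.*9")
})

test_that("simulated probabilities are monotone in each positive-beta input", {
  co <- riskCoefficients(-17, 0.7, 1.2, 2)
  O <- seq(0.05, 1, length.out = 20)
  expect_true(all(diff(collisionRate(O, 1000, 60, co)) > 0))
  V <- seq(100, 20000, length.out = 20)
  expect_true(all(diff(collisionRate(0.5, V, 60, co)) > 0))
  S <- seq(40, 110, length.out = 20)
  expect_true(all(diff(collisionRate(0.5, 1000, S, co)) > 0))
  p <- -expm1(-collisionRate(runif(100, 0.01, 1), rlogunif(100, 50, 5e3),
                             runif(100, 30, 120), co))
  expect_true(all(p >= 0 & p < 1))
})

test_that("scene generation is a pure function of config, truth and seed", {
  cfg <- smallConfig(seed = 33L)
  s1 <- generateScene(cfg)
  s2 <- generateScene(cfg)
  expect_identical(segmentTable(s1), segmentTable(s2))
  expect_identical(s1@rasters, s2@rasters)
  expect_identical(s1@presences, s2@presences)
  expect_identical(s1@collisionRecords, s2@collisionRecords)
  # unit-slope truth: rate equals a * O * V * S exactly
  st <- segmentTable(s1)
  a <- proportionalityConstant(sceneTruth(s1)@riskCoefs)
  expect_equal(st$rate, a * st$O * st$V * st$S, tolerance = 1e-12)
  # outcomes attach to existing segments; presences inside extent
  expect_true(validObject(s1))
})

test_that("road networks respect class mix, determinism and extent", {
  cfg <- smallConfig(seed = 44L)
  allLocal <- sceneConfig(extent = cfg@extent, covariateNames = "Z",
                          nRoads = 20L,
                          roadClassMix = c(freeway = 0, highway = 0,
                                           arterial = 0, subarterial = 0,
                                           collector = 0, local = 1),
                          seed = 1L)
  net <- generateRoadNetwork(allLocal)
  expect_true(all(net@roadClass == "local"))
  expect_identical(generateRoadNetwork(cfg), generateRoadNetwork(cfg))
  e <- cfg@extent
  for (m in generateRoadNetwork(cfg)@coords) {
    expect_true(all(m[, 1] >= e[1] & m[, 1] <= e[2]))
    expect_true(all(m[, 2] >= e[3] & m[, 2] <= e[4]))
  }
  # empirical class frequencies inside exact per-class 99% binomial CIs
  mix <- c(freeway = 0.1, highway = 0.1, arterial = 0.2,
           subarterial = 0.2, collector = 0.2, local = 0.2)
  bigCfg <- sceneConfig(extent = c(0, 5e4, 0, 5e4), covariateNames = "Z",
                        nRoads = 50L, roadClassMix = mix, seed = 2L)
  counts <- table(factor(generateRoadNetwork(bigCfg)@roadClass,
                         levels = roadClasses()))
  for (cl in roadClasses()) {
    lo <- qbinom(0.005, 50, mix[[cl]])
    hi <- qbinom(0.995, 50, mix[[cl]])
    expect_gte(counts[[cl]], lo)
    expect_lte(counts[[cl]], hi)
  }
})

test_that("scene writer emits the documented plain-text artifacts", {
  scene <- smallScene()
  dir <- withr::local_tempdir()
  writeScene(scene, dir)
  files <- list.files(dir)
  expect_true(all(c("ELEV.asc", "network.geojson", "segments.csv",
                    "traffic_obs.csv", "presences.geojson",
                    "collision_records.geojson",
                    "scene_manifest.json") %in% files))
  man <- jsonlite::fromJSON(file.path(dir, "scene_manifest.json"))
  expect_equal(man$config$seed, scene@config@seed)
  expect_equal(man$truth$risk_coefs$beta1, 1)
  back <- readAsciiGrid(file.path(dir, "ELEV.asc"), "ELEV")
  expect_equal(rasterValues(back), rasterValues(scene@rasters$ELEV),
               tolerance = 1e-12)
})
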