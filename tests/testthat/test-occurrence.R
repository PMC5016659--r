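# Independent oracle: apply the pruning rule (drop the larger-mean-|r|
# member of the most correlated offending pair) recursively on the
# correlation matrix itself.
pruneOracle <- function(df, threshold) {
  keep <- names(df)
  repeat {
    if (length(keep) < 2L) return(keep)
    r <- abs(cor(df[keep])); diag(r) <- 0
    if (max(r) < threshold) return(keep)
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    m <- rowMeans(r[pair, , drop = FALSE])
    keep <- setdiff(keep, if (m[1] > m[2]) pair[1] else pair[2])
  }
}

test_that("correlation pruning enforces the pairwise threshold", {
  set.seed(8)
  base <- data.frame(a = rnorm(500))
  base$b <- base$a                      # r = 1 duplicate
  base$c <- rnorm(500)
  out <- correlationPrune(base, 0.75)
  expect_length(intersect(c("a", "b"), names(out$table)), 1L)
  expect_true("c" %in% names(out$table))
  # all pairwise |r| already below threshold: unchanged
  ind <- data.frame(x = rnorm(300), y = rnorm(300), z = rnorm(300))
  expect_identical(correlationPrune(ind, 0.75)$table, ind)
  # six columns with a planted correlation structure vs the oracle
  z1 <- rnorm(800); z2 <- rnorm(800)
  six <- data.frame(v1 = z1, v2 = z1 + 0.3 * rnorm(800),
                    v3 = z1 + 0.6 * rnorm(800),
                    v4 = z2, v5 = z2 + 0.4 * rnorm(800),
                    v6 = rnorm(800))
  got <- correlationPrune(six, 0.75)
  expect_identical(names(got$table), pruneOracle(six, 0.75))
  expect_true(max(abs(cor(got$table))[upper.tri(diag(ncol(got$table)))]) <
                0.75)
  # constant column dropped with a warning
  expect_warning(cc <- correlationPrune(cbind(ind, k = 1), 0.75),
                 "constant")
  expect_false("k" %in% names(cc$table))
})

test_that("boosted trees separate a perfectly informative covariate", {
  set.seed(9)
  n <- 600
  x <- rnorm(n)
  train <- data.frame(label = as.integer(x > 0), x = x, noise = rnorm(n))
  fit <- fitOccurrence(train, maxTrees = 2000L, nFolds = 5L, seed = 2L)
  expect_gt(fit@devianceExplained, 90)
  expect_gt(cvAuc(fit)[["mean"]], 0.99)
  expect_error(fitOccurrence(data.frame(label = rep(1L, 50), x = rnorm(50))),
               "both presence and background")
})

test_that("permuted labels yield chance-level cross-validated AUC", {
  set.seed(10)
  n <- 5000
  train <- data.frame(label = sample(rep(0:1, c(4000, 1000))),
                      a = rnorm(n), b = rnorm(n))
  fit <- fitOccurrence(train, maxTrees = 500L, nFolds = 5L, seed = 3L)
  expect_lt(abs(cvAuc(fit)[["mean"]] - 0.5), 0.05)
})

test_that("a strong logistic truth is recovered with matching response signs", {
  fx <- occFixture()
  fit <- fx$fit
  train <- fx$train
  expect_gt(cvAuc(fit)[["mean"]], 0.8)
  # partial-dependence slope signs match the true coefficient signs
  pd <- partialDependence(fit)
  slope <- function(d) coef(lm(response ~ value, d))[["value"]]
  expect_gt(slope(pd$ELEV), 0)
  expect_lt(slope(pd$GREEN), 0)
  # contributions are a proper percentage decomposition
  expect_equal(sum(variableContributions(fit)), 100, tolerance = 0.1)
  expect_true(all(variableContributions(fit) >= 0))
  # covariate order does not change the fit
  fit2 <- fitOccurrence(train[, c("label", "GREEN", "ELEV")],
                        maxTrees = 1500L, nFolds = 5L, seed = 6L)
  expect_equal(fit2@devianceExplained, fit@devianceExplained,
               tolerance = 1e-8)
})

test_that("raster prediction equals the row-by-row model application", {
  fx <- occFixture()
  fit <- fx$fit
  rasters <- fx$rasters
  pred <- predictOccurrenceRaster(fit, rasters)
  v <- rasterValues(pred)
  expect_true(all(v > 0 & v < 1))
  # per-cell oracle: predict on each cell's covariate row independently
  set.seed(12)
  cells <- sample(length(v), 50)
  rows <- data.frame(ELEV = as.vector(rasterValues(rasters$ELEV))[cells],
                     GREEN = as.vector(rasterValues(rasters$GREEN))[cells])
  expect_equal(as.vector(v)[cells], unname(predictOccurrence(fit, rows)),
               tolerance = 1e-10)
  # constant rasters give the constant prediction of that covariate row
  const <- list(
    ELEV = covariateRaster("ELEV", matrix(0.3, 4, 4), c(0, 0), 1000),
    GREEN = covariateRaster("GREEN", matrix(-1.2, 4, 4), c(0, 0), 1000))
  cp <- rasterValues(predictOccurrenceRaster(fit, const))
  expect_equal(max(cp) - min(cp), 0)
  expect_equal(cp[1, 1],
               unname(predictOccurrence(
                 fit, data.frame(ELEV = 0.3, GREEN = -1.2))),
               tolerance = 1e-12)
  expect_error(predictOccurrenceRaster(fit, const["ELEV"]), "GREEN")
})
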