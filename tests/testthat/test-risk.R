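test_that("cloglog link matches its analytic values and round-trips", {
  expect_equal(cloglog(-expm1(-1)), 0, tolerance = 1e-12)
  expect_equal(cloglog(0.5), -0.36651292058166433, tolerance = 1e-12)
  expect_equal(cloglogInv(0), 0.6321205588285577, tolerance = 1e-12)
  expect_equal(cloglogInv(log(log(2))), 0.5, tolerance = 1e-12)
  p <- c(1e-9, 1e-6, 0.01, 0.3, 0.5, 0.9, 1 - 1e-6, 1 - 1e-9)
  expect_equal(cloglogInv(cloglog(p)), p, tolerance = 1e-10)
  expect_lt(cloglogInv(-40), 1e-15)
  expect_gt(cloglogInv(40), 1 - 1e-15)
  expect_error(cloglog(0), "strictly inside")
  expect_error(cloglog(1), "strictly inside")
  expect_error(cloglogInv(Inf), "finite")
})

test_that("collision rate reproduces the multiplicative form exactly", {
  expect_equal(collisionRate(1, 1, 1, riskCoefficients(0, 1, 1, 1)), 1)
  expect_equal(collisionRate(0.5, 4, 2, riskCoefficients(log(2), 1, 1, 1)),
               8, tolerance = 1e-12)
  # published-style coefficients vs a 40-digit arithmetic oracle
  co <- riskCoefficients(-12.82, 0.6583, 0.2715, 2.694)
  expect_equal(collisionRate(0.5, 2000, 100, co), 3.299182497838189,
               tolerance = 1e-12)
  expect_error(collisionRate(0, 100, 60, co), "strictly positive")
  expect_error(collisionRate(0.5, 100, -1, co), "strictly positive")
  expect_error(collisionRate(1.2, 100, 60, co), "must not exceed 1")
  # unit slopes: rate identically e^beta0 * O * V * S
  O <- runif(50, 0.01, 1); V <- rlogunif(50, 10, 1e5); S <- runif(50, 30, 120)
  expect_equal(collisionRate(O, V, S, riskCoefficients(-11, 1, 1, 1)),
               exp(-11) * O * V * S, tolerance = 1e-12)
})

test_that("the cloglog GLM recovers simulated coefficients", {
  recs <- simulateRecords(20000, riskCoefficients(-11, 1, 1, 1), seed = 71)
  fit <- fitCollisionGlm(recs)
  b <- riskBetas(riskCoefficientsOf(fit))
  expect_equal(unname(b[-1]), c(1, 1, 1), tolerance = 0.1)
  # link consistency: fitted probabilities equal cloglogInv(eta)
  eta <- as.numeric(predict(fit@model, type = "link"))
  expect_equal(unname(fit@model$fitted.values), cloglogInv(eta),
               tolerance = 1e-10)
  # AIC identity against the direct log-likelihood
  expect_equal(modelAic(fit), -2 * as.numeric(logLik(fit@model)) + 2 * 4,
               tolerance = 1e-8)
})

test_that("an outcome independent of the predictors fits nothing", {
  recs <- simulateRecords(10000, riskCoefficients(-11, 1, 1, 1), seed = 72)
  recs$Y <- withr::with_seed(73, sample(recs$Y))
  fit <- fitCollisionGlm(recs)
  expect_lt(devianceExplained(fit), 1)
  expect_true(all(abs(fit@coefficients[-1, "z"]) < 4))
})

test_that("degenerate designs are rejected with diagnostics", {
  recs <- simulateRecords(500, riskCoefficients(-11, 1, 1, 1), seed = 74)
  recs$dup <- log(recs$V)
  recs$lnVcopy <- log(recs$V)
  expect_error(
    fitAlternativeGlm(cbind(recs, A = log(recs$V), B = log(recs$V)),
                      c("A", "B")),
    "aliased")
  oneClass <- recs
  oneClass$Y <- 0L
  expect_error(fitCollisionGlm(oneClass), "both outcome classes")
})

test_that("alternative-model metrics are invariant to predictor order", {
  scene <- smallScene()
  st <- segmentTable(scene)
  d <- data.frame(Y = st$Y, RDCLASS = st$RDCLASS, KMTODEV = st$KMTODEV,
                  POPDENS = st$POPDENS)
  f1 <- fitAlternativeGlm(d, c("RDCLASS", "KMTODEV", "POPDENS"))
  f2 <- fitAlternativeGlm(d, c("POPDENS", "RDCLASS", "KMTODEV"))
  expect_equal(devianceExplained(f1), devianceExplained(f2),
               tolerance = 1e-10)
  expect_equal(modelAic(f1), modelAic(f2), tolerance = 1e-10)
})

test_that("sequential deviance shares are conserved and match nested fits", {
  recs <- simulateRecords(3000,
                          riskCoefficients(calibratedBeta0(0.8, 1.1, 1.5),
                                           0.8, 1.1, 1.5),
                          seed = 75)
  fit <- fitCollisionGlm(recs)
  orders <- list(c("lnO", "lnV", "lnS"), c("lnS", "lnO", "lnV"),
                 c("lnV", "lnS", "lnO"))
  for (ord in orders) {
    sh <- sequentialDevianceAnova(fit, ord)
    expect_equal(sum(sh), 1, tolerance = 1e-10)
    expect_identical(names(sh), ord)
  }
  # independent nested-deviance oracle via stats::anova
  d <- fit@model$model
  a <- anova(glm(Y ~ lnS + lnO + lnV, binomial(link = "cloglog"), d))
  oracle <- a$Deviance[-1] / sum(a$Deviance[-1])
  expect_equal(unname(sequentialDevianceAnova(fit, c("lnS", "lnO", "lnV"))),
               oracle, tolerance = 1e-8)
  expect_error(sequentialDevianceAnova(fit, c("lnO", "lnV")), "permutation")
})

test_that("single-term decomposition assigns the full share", {
  recs <- simulateRecords(2000, riskCoefficients(-11, 1, 1, 1), seed = 76)
  d <- data.frame(Y = recs$Y, lnO = log(recs$O))
  sh <- wvcrisk:::sequentialDevianceShares(d, "lnO", "lnO")
  expect_equal(unname(sh), 1, tolerance = 1e-12)
})

test_that("rank-based AUC equals pair counting and external references", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  set.seed(77)
  scores <- rnorm(5000); labels <- rbinom(5000, 1, 0.4)
  expect_lt(abs(rocAuc(scores, labels) - 0.5), 0.05)
  # ties: exhaustive pair-counting oracle
  s <- c(1, 2, 2, 3, 3, 3, 5); l <- c(0, 0, 1, 0, 1, 1, 1)
  pos <- which(l == 1); neg <- which(l == 0)
  cnt <- 0
  for (i in pos) for (j in neg)
    cnt <- cnt + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(rocAuc(s, l), cnt / (length(pos) * length(neg)))
  expect_equal(rocAuc(scores, labels),
               as.numeric(pROC::auc(labels, scores, quiet = TRUE)),
               tolerance = 1e-12)
  expect_error(rocAuc(scores, rep(1, 5000)), "both classes")
})
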