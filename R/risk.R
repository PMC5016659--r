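#' Coefficients of the multiplicative collision-risk model
#'
#' The collision rate on segment \eqn{i} is modeled as
#' \deqn{C_i = \exp(\beta_0 + \beta_1 \ln O_i + \beta_2 \ln V_i +
#'   \beta_3 \ln S_i)}
#' where \eqn{O_i} is the relative likelihood of species occurrence
#' (exposure), and \eqn{V_i} (traffic volume, vehicles/day) and \eqn{S_i}
#' (speed, km/h) jointly form the hazard. Under exact proportionality of
#' risk to exposure times hazard, \eqn{\beta_1 = \beta_2 = \beta_3 = 1} and
#' \eqn{e^{\beta_0}} is the constant of proportionality.
#'
#' @slot beta0 intercept (log constant of proportionality).
#' @slot beta1 coefficient on \eqn{\ln O} (exposure).
#' @slot beta2 coefficient on \eqn{\ln V} (volume).
#' @slot beta3 coefficient on \eqn{\ln S} (speed).
#' @export
setClass("RiskCoefficients",
  representation(beta0 = "numeric", beta1 = "numeric",
                 beta2 = "numeric", beta3 = "numeric"),
  validity = function(object) {
    b <- c(object@beta0, object@beta1, object@beta2, object@beta3)
    if (length(b) != 4L || any(!is.finite(b)))
      return("all four coefficients must be finite scalars")
    TRUE
  })

#' @rdname RiskCoefficients-class
#' @param beta0,beta1,beta2,beta3 model coefficients.
#' @export
riskCoefficients <- function(beta0, beta1 = 1, beta2 = 1, beta3 = 1) {
  new("RiskCoefficients", beta0 = as.numeric(beta0),
      beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      beta3 = as.numeric(beta3))
}

#' @rdname RiskCoefficients-class
#' @param x a \code{RiskCoefficients}.
#' @return \code{riskBetas} returns the named numeric vector
#'   c(beta0, beta1, beta2, beta3); \code{proportionalityConstant} returns
#'   \eqn{e^{\beta_0}}.
#' @export
riskBetas <- function(x) {
  c(beta0 = x@beta0, beta1 = x@beta1, beta2 = x@beta2, beta3 = x@beta3)
}

#' @rdname RiskCoefficients-class
#' @export
proportionalityConstant <- function(x) exp(x@beta0)

setMethod("show", "RiskCoefficients", function(object) {
  cat(sprintf(
    "RiskCoefficients: beta0 = %.4g, beta1 (ln O) = %.4g, beta2 (ln V) = %.4g, beta3 (ln S) = %.4g\n",
    object@beta0, object@beta1, object@beta2, object@beta3))
})

#' Complementary log-log link and its inverse
#'
#' \code{cloglog(p)} returns \eqn{\ln(-\ln(1-p))}; under a Poisson encounter
#' process with rate \eqn{C}, the probability of at least one collision is
#' \eqn{p = 1 - e^{-C}}, so \code{cloglog(p)} recovers \eqn{\ln C} — the
#' link that makes the binary collision GLM linear in the log predictors.
#'
#' @param p probability strictly inside (0, 1).
#' @return \code{cloglog} returns the link value; \code{cloglogInv} its
#'   inverse, a probability in (0, 1).
#' @export
cloglog <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  log(-log1p(-p))
}

#' @rdname cloglog
#' @param eta finite real linear predictor.
#' @export
cloglogInv <- function(eta) {
  if (any(!is.finite(eta)))
    stop("eta must be finite", call. = FALSE)
  -expm1(-exp(eta))
}

#' Collision rate of the Poisson encounter model
#'
#' @param O relative occurrence likelihood in (0, 1].
#' @param V traffic volume in vehicles/day, > 0.
#' @param S traffic speed in km/h, > 0.
#' @param coefs a \linkS4class{RiskCoefficients}.
#' @return the nonnegative rate \eqn{C_i} per segment.
#' @export
collisionRate <- function(O, V, S, coefs) {
  checkPositive(O, "occurrence O")
  stopIfNot(all(O <= 1), "occurrence O must not exceed 1")
  checkPositive(V, "traffic volume V")
  checkPositive(S, "traffic speed S")
  exp(coefs@beta0 + coefs@beta1 * log(O) + coefs@beta2 * log(V) +
      coefs@beta3 * log(S))
}

#' Simulate binary collision outcomes from the encounter model
#'
#' Computes the rate \eqn{C_i} for every segment, maps it to the collision
#' probability \eqn{p_i = 1 - e^{-C_i}}, and draws
#' \eqn{Y_i \sim \mathrm{Bernoulli}(p_i)}.
#'
#' @param O,V,S per-segment occurrence, volume and speed (see
#'   \code{\link{collisionRate}}).
#' @param coefs a \linkS4class{RiskCoefficients}.
#' @param seed integer seed.
#' @param segmentId optional ids used in error messages and the output.
#' @return data.frame with \code{segment_id}, \code{rate}, \code{prob} and
#'   the binary outcome \code{Y}.
#' @export
simulateCollisions <- function(O, V, S, coefs, seed = 1L,
                               segmentId = seq_along(O)) {
  checkPositive(V, "traffic volume V", segmentId)
  checkPositive(S, "traffic speed S", segmentId)
  rate <- collisionRate(O, V, S, coefs)
  p <- -expm1(-rate)
  y <- withSubSeed(seed, "collision-draws",
                   rbinom(length(p), 1L, p))
  data.frame(segment_id = segmentId, rate = rate, prob = p, Y = y)
}

#' Fitted collision model
#'
#' Holds the maximum-likelihood binomial GLM with cloglog link, its
#' coefficient table, deviance decomposition, AIC and (after validation)
#' hold-out ROC.
#'
#' @slot model the underlying \code{glm} fit.
#' @slot coefficients coefficient matrix (Estimate, SE, z, p).
#' @slot devianceExplained percent of null deviance explained.
#' @slot aic Akaike information criterion.
#' @slot anova named sequential deviance-reduction shares (sum to 1).
#' @slot termOrder order in which terms entered the ANOVA decomposition.
#' @slot kind "structured" (ln O, ln V, ln S) or "alternative" (flat
#'   covariate set).
#' @export
setClass("CollisionFit",
  representation(model = "ANY", coefficients = "matrix",
                 devianceExplained = "numeric", aic = "numeric",
                 anova = "numeric", termOrder = "character",
                 kind = "character"))

setMethod("show", "CollisionFit", function(object) {
  cat(sprintf("CollisionFit (%s): deviance explained %.1f%%, AIC %.1f\n",
              object@kind, object@devianceExplained, object@aic))
  printCoefmat(object@coefficients, digits = 4L)
  cat("Sequential ANOVA shares:\n")
  print(round(object@anova, 4L))
})

#' @rdname CollisionFit-class
#' @param x a \code{CollisionFit}.
#' @export
riskCoefficientsOf <- function(x) {
  stopIfNot(x@kind == "structured",
            "risk coefficients are defined for the structured model only")
  b <- x@coefficients[, "Estimate"]
  riskCoefficients(b[["(Intercept)"]], b[["lnO"]], b[["lnV"]], b[["lnS"]])
}

#' @rdname CollisionFit-class
#' @export
devianceExplained <- function(x) x@devianceExplained

#' @rdname CollisionFit-class
#' @export
modelAic <- function(x) x@aic

# Shared GLM driver for the structured and alternative collision models.
fitCloglogGlm <- function(data, terms, kind, termOrder = terms) {
  stopIfNot(all(c(0, 1) %in% data$Y), "both outcome classes must be present")
  stopIfNot(setequal(termOrder, terms) && length(termOrder) == length(terms),
            "termOrder must be a permutation of the model terms")
  fml <- as.formula(paste("Y ~", paste(terms, collapse = " + ")))
  fit <- glm(fml, family = binomial(link = "cloglog"), data = data,
             control = list(epsilon = 1e-8, maxit = 100L))
  if (!fit$converged)
    stop("collision GLM did not converge (possible complete separation); ",
         "largest |coefficient| = ",
         format(max(abs(coef(fit))), digits = 3), call. = FALSE)
  if (anyNA(coef(fit)))
    stop("rank-deficient design: aliased term(s) ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  if (max(abs(coef(fit))) > 1e3)
    stop("diverging coefficients indicate complete separation", call. = FALSE)
  sm <- summary(fit)$coefficients
  colnames(sm) <- c("Estimate", "SE", "z", "Pr(>|z|)")
  dev <- 100 * (fit$null.deviance - fit$deviance) / fit$null.deviance
  shares <- sequentialDevianceShares(data, terms, termOrder)
  new("CollisionFit", model = fit, coefficients = sm,
      devianceExplained = dev, aic = fit$aic, anova = shares,
      termOrder = termOrder, kind = kind)
}

#' Fit the structured collision GLM
#'
#' Binomial GLM with complementary log-log link on the log-transformed
#' submodel predictions \eqn{\ln O}, \eqn{\ln V}, \eqn{\ln S} — the direct
#' statistical translation of the multiplicative rate model. Occurrence is
#' clamped below at \code{oFloor} before logging.
#'
#' @param records data.frame with columns \code{O}, \code{V}, \code{S} and
#'   binary \code{Y}.
#' @param termOrder order of terms for the sequential deviance
#'   decomposition; defaults to exposure first, then volume, then speed.
#' @param oFloor lower clamp for O before the log transform (default 1e-6).
#' @return a \linkS4class{CollisionFit}.
#' @export
fitCollisionGlm <- function(records, termOrder = c("lnO", "lnV", "lnS"),
                            oFloor = 1e-6) {
  checkPositive(records$V, "traffic volume V", records$segment_id)
  checkPositive(records$S, "traffic speed S", records$segment_id)
  stopIfNot(all(records$O > 0 & records$O <= 1),
            "occurrence O must lie in (0, 1]")
  d <- data.frame(Y = records$Y,
                  lnO = log(pmax(records$O, oFloor)),
                  lnV = log(records$V),
                  lnS = log(records$S))
  fitCloglogGlm(d, c("lnO", "lnV", "lnS"), "structured", termOrder)
}

#' Fit the flat "alternative" collision GLM
#'
#' The comparison model that regresses the collision outcome directly on
#' the raw (untransformed) covariates used by all submodels, with the same
#' cloglog link — emulating single-model collision analyses so the
#' structured framework can be compared on AIC, deviance explained and
#' hold-out ROC.
#'
#' @param records data.frame with binary \code{Y} and the raw covariate
#'   columns.
#' @param covariates names of the covariate columns to include.
#' @param termOrder order for the sequential ANOVA (default: as given).
#' @return a \linkS4class{CollisionFit}.
#' @export
fitAlternativeGlm <- function(records, covariates,
                              termOrder = covariates) {
  stopIfNot(all(covariates %in% names(records)),
            paste("missing covariate column(s):",
                  paste(setdiff(covariates, names(records)), collapse = ", ")))
  d <- records[, c("Y", covariates), drop = FALSE]
  fitCloglogGlm(d, covariates, "alternative", termOrder)
}

# Nested-refit sequential decomposition: share_k = deviance drop when term k
# is added (in termOrder) over the total drop of the full model.
sequentialDevianceShares <- function(data, terms, termOrder) {
  devs <- numeric(length(termOrder) + 1L)
  null <- glm(Y ~ 1, family = binomial(link = "cloglog"), data = data)
  devs[1L] <- null$deviance
  for (k in seq_along(termOrder)) {
    fml <- as.formula(paste("Y ~", paste(termOrder[seq_len(k)],
                                         collapse = " + ")))
    devs[k + 1L] <- glm(fml, family = binomial(link = "cloglog"),
                        data = data,
                        control = list(epsilon = 1e-8, maxit = 100L))$deviance
  }
  drops <- -diff(devs)
  total <- devs[1L] - devs[length(devs)]
  setNames(drops / total, termOrder)
}

#' Sequential deviance ANOVA of a collision fit
#'
#' Re-expresses model fit as per-term shares of the total deviance
#' reduction when terms are added one at a time in the given order (the
#' decomposition is order-dependent; the default order is exposure, volume,
#' speed). Shares are nonnegative up to sampling noise and sum to 1.
#'
#' @param fit a \linkS4class{CollisionFit}.
#' @param termOrder permutation of the model's terms.
#' @return named numeric vector of shares summing to 1.
#' @export
sequentialDevianceAnova <- function(fit, termOrder = fit@termOrder) {
  terms <- rownames(fit@coefficients)
  terms <- terms[terms != "(Intercept)"]
  stopIfNot(setequal(termOrder, terms) && length(termOrder) == length(terms),
            "termOrder must be a permutation of the fitted terms")
  sequentialDevianceShares(fit@model$model, terms, termOrder)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counting one half (the rank-sum estimator).
#'
#' @param scores numeric predictions, higher = more positive.
#' @param labels binary outcomes (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
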