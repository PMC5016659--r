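# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats anova aggregate as.formula binomial coef glm logLik
#'   plogis predict printCoefmat qnorm quantile rbinom rnorm runif sd
#'   setNames var
#' @importFrom utils head read.csv write.csv
NULL

# Derive a reproducible sub-seed for a named random substream, so that e.g.
# changing the number of roads does not perturb raster generation. The hash
# is a plain polynomial rolling hash; result always fits a 32-bit integer.
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1048573
  as.integer((abs(seed) %% 1000003) * 2048 + h) %% 2147483629L
}

withSubSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(subSeed(seed, stream))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

stopIfNot <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Positive-part check with offender naming, used by the simulators and the
# rate computation (logs of nonpositive values are undefined).
checkPositive <- function(x, what, ids = seq_along(x)) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop(sprintf("%s must be strictly positive; offending segment(s): %s",
                 what, paste(head(ids[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
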