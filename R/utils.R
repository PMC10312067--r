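#' @useDynLib mixtree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize plogis qlogis rnorm runif rbinom sd var predict
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.  All stochastic entry points route through this so the
# package never leaks RNG state and is bitwise reproducible under a fixed seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# probability floor used everywhere a logit is taken
.PROB_EPS <- 0.001

`%||%` <- function(a, b) if (is.null(a)) b else a
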