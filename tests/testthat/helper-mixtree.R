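# Shared fixtures, all built in code.

# tiny deterministic dataset: p exposures on (0, 1.5), q covariates, linear y
make_dataset <- function(n = 50, p = 3, q = 2, seed = 1,
                         y_fun = function(A, W) rowSums(W) + stats::rnorm(nrow(A), 0, 0.1)) {
  set.seed(seed)
  A <- matrix(stats::runif(n * p, 0, 1.5), n, p,
              dimnames = list(NULL, paste0("a", seq_len(p))))
  W <- matrix(stats::rnorm(n * q), n, q,
              dimnames = list(NULL, if (q > 0) paste0("w", seq_len(q)) else NULL))
  y <- y_fun(A, W)
  mixture_dataset(as.data.frame(A), if (q > 0) as.data.frame(W) else NULL, y)
}

# random interval rule on the exposures of `data`
random_rule <- function(data, seed) {
  set.seed(seed)
  vars <- sample(colnames(data$exposures), sample(ncol(data$exposures), 1))
  lowers <- numeric(0); uppers <- numeric(0)
  for (v in vars) {
    b <- sort(stats::runif(2, -0.5, 2))
    lo <- if (stats::runif(1) < 0.3) -Inf else b[1]
    hi <- if (stats::runif(1) < 0.3) Inf else b[2]
    if (!is.finite(lo) && !is.finite(hi)) hi <- b[2]
    lowers <- c(lowers, lo); uppers <- c(uppers, hi)
  }
  mixture_rule(vars, lowers, uppers)
}

# brute-force row-by-row oracle for rule evaluation
brute_force_indicator <- function(rule, data) {
  n <- length(data$outcome)
  out <- integer(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (k in seq_len(nrow(rule$predicates))) {
      a <- data$exposures[i, rule$predicates$var[k]]
      if (!(a > rule$predicates$lower[k] && a <= rule$predicates$upper[k])) {
        ok <- FALSE
        break
      }
    }
    out[i] <- as.integer(ok)
  }
  out
}

# hand-built nuisance_fit (for targeting tests on the [0,1] scale)
manual_nuisance <- function(Q0, Q1, g1, scale = c(0, 1),
                            outcome_type = "continuous") {
  structure(
    list(Q0 = Q0, Q1 = Q1, g1 = g1, g_bounds = c(0.001, 0.999),
         outcome_scale = scale, outcome_type = outcome_type),
    class = "nuisance_fit"
  )
}

# random targeting instance with an interior epsilon
random_target_instance <- function(seed, m = 150) {
  set.seed(seed)
  g1 <- stats::runif(m, 0.15, 0.85)
  a <- stats::rbinom(m, 1, g1)
  Q0 <- stats::runif(m, 0.2, 0.8)
  Q1 <- stats::runif(m, 0.2, 0.8)
  y <- clip_unit(ifelse(a == 1, Q1, Q0) + stats::rnorm(m, 0, 0.15))
  list(nuisance = manual_nuisance(Q0, Q1, g1), a = a, y = y)
}

clip_unit <- function(x) pmin(pmax(x, 0.01), 0.99)

# small fast learner library used by heavier simulation loops
lib_fast <- function() {
  list(
    learner_spec("mean", "mean"),
    learner_spec("linear", "linear"),
    learner_spec("tree_d3", "tree", max_depth = 3, min_leaf_frac = 0.05)
  )
}

lib_lin <- function() {
  list(learner_spec("mean", "mean"), learner_spec("linear", "linear"))
}

fast_config <- function(seed, V = 5L, do_components = FALSE, ...) {
  mixtree_config(V = V, seed = seed, w_library = lib_fast(),
                 do_components = do_components, ...)
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
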