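test_that("saturated nuisance reduces targeting to the plug-in difference of means", {
  set.seed(1)
  m <- 80
  a <- rbinom(m, 1, 0.5)
  y <- clip_unit(0.3 + 0.25 * a + rnorm(m, 0, 0.05))
  mu1 <- mean(y[a == 1]); mu0 <- mean(y[a == 0])
  nuis <- manual_nuisance(rep(mu0, m), rep(mu1, m), rep(mean(a), m))
  tg <- target_ate(nuis, a, y)
  expect_equal(tg$epsilon, 0, tolerance = 1e-8)
  expect_equal(tg$result$psi, mu1 - mu0, tolerance = 1e-10)
})

test_that("targeting solves the EIC score equation", {
  for (s in 1:25) {
    inst <- random_target_instance(s)
    tg <- target_ate(inst$nuisance, inst$a, inst$y)
    expect_lt(abs(mean(tg$result$eic)), 1e-8)
    r <- tg$result
    expect_lte(r$ci_lower, r$psi)
    expect_gte(r$ci_upper, r$psi)
    expect_equal(r$ci_upper - r$psi, 1.96 * r$se, tolerance = 1e-12)
  }
})

test_that("epsilon matches a brute-force grid maximizer", {
  grid_eps <- function(H, offset, y, lo = -5, hi = 5, step = 1e-4) {
    best <- NA_real_; best_ll <- -Inf
    for (chunk in split(seq(lo, hi, by = step),
                        ceiling(seq_along(seq(lo, hi, by = step)) / 4000))) {
      P <- plogis(outer(offset, chunk, function(o, e) o) +
                  outer(H, chunk))
      ll <- colSums(y * log(P) + (1 - y) * log(1 - P))
      if (max(ll) > best_ll) { best_ll <- max(ll); best <- chunk[which.max(ll)] }
    }
    best
  }
  for (s in 1:5) {
    inst <- random_target_instance(s, m = 120)
    H <- inst$a / inst$nuisance$g1 - (1 - inst$a) / (1 - inst$nuisance$g1)
    offset <- qlogis(ifelse(inst$a == 1, inst$nuisance$Q1, inst$nuisance$Q0))
    tg <- target_ate(inst$nuisance, inst$a, inst$y)
    expect_lt(abs(tg$epsilon - grid_eps(H, offset, inst$y)), 2e-4)
  }
})

test_that("nuisance fitting honours the no-covariate and truncation contracts", {
  # no covariates: g is the (clipped) indicator rate; Q0/Q1 are class means
  d <- make_dataset(n = 200, p = 2, q = 0, seed = 31,
                    y_fun = function(A, W) 2 * (A[, 1] > 0.7) + rnorm(nrow(A), 0, 0.3))
  rule <- mixture_rule("a1", 0.7, Inf)
  folds <- assign_folds(200, 2, seed = 1)
  param <- mixtree:::subset_dataset(d, fold_param_idx(folds, 1))
  est <- mixtree:::subset_dataset(d, fold_est_idx(folds, 1))
  nu <- fit_nuisance(param, rule, est,
                     w_library = list(learner_spec("linear", "linear")), seed = 5)
  a_param <- evaluate_rule(rule, param)
  expect_equal(unique(round(nu$g1, 10)), round(mean(a_param), 10))
  ysc <- (param$outcome - nu$outcome_scale[1]) / diff(nu$outcome_scale)
  expect_equal(unique(round(nu$Q1, 6)), round(mean(ysc[a_param == 1]), 6))
  expect_equal(unique(round(nu$Q0, 6)), round(mean(ysc[a_param == 0]), 6))

  # strongly separable propensity: every g1 ends on a truncation bound
  set.seed(32)
  n <- 200
  w1 <- sample(c(-3, 3), n, TRUE)
  A <- data.frame(a1 = runif(n, 0, 1.5) + 2 * (w1 > 0))
  ds <- mixture_dataset(A, data.frame(w1 = w1), rnorm(n))
  rule2 <- mixture_rule("a1", 2, Inf)
  folds2 <- assign_folds(n, 2, seed = 2)
  p2 <- mixtree:::subset_dataset(ds, fold_param_idx(folds2, 1))
  e2 <- mixtree:::subset_dataset(ds, fold_est_idx(folds2, 1))
  nu2 <- fit_nuisance(p2, rule2, e2, w_library = lib_lin(), seed = 6)
  expect_true(all(nu2$g1 %in% c(0.025, 0.975)))

  # positivity guard: a one-sided rule raises the positivity condition
  expect_error(
    fit_nuisance(param, mixture_rule("a1", -Inf, Inf), est, w_library = lib_lin()),
    class = "mixtree_positivity_error"
  )
})

test_that("psi is equivariant under affine outcome rescaling", {
  d <- make_dataset(n = 300, p = 2, q = 2, seed = 41,
                    y_fun = function(A, W) {
                      3 * (A[, 1] > 0.6) + W[, 1] + rnorm(nrow(A), 0, 0.2)
                    })
  d2 <- d
  d2$outcome <- 10 * d$outcome + 3
  rule <- mixture_rule("a1", 0.6, Inf)
  folds <- assign_folds(300, 2, seed = 3)
  run_one <- function(dd) {
    param <- mixtree:::subset_dataset(dd, fold_param_idx(folds, 1))
    est <- mixtree:::subset_dataset(dd, fold_est_idx(folds, 1))
    nu <- fit_nuisance(param, rule, est, w_library = lib_fast(), seed = 9)
    target_ate(nu, evaluate_rule(rule, est), est$outcome)$result$psi
  }
  expect_equal(run_one(d2), 10 * run_one(d), tolerance = 1e-6)
})

test_that("with a known rule, no confounding and true g the estimator is unbiased with nominal coverage", {
  reps <- 100L
  err <- numeric(reps)
  cover <- logical(reps)
  rule <- mixture_rule(c("a1", "a2"), c(0.5, 0.5), c(Inf, Inf))
  p_true <- (1 - 0.5 / 1.5)^2          # P(a1 > .5, a2 > .5) under U(0, 1.5)
  for (s in seq_len(reps)) {
    d <- make_dataset(n = 500, p = 3, q = 2, seed = 7000 + s,
                      y_fun = function(A, W) {
                        5 * (A[, 1] > 0.5) * (A[, 2] > 0.5) + W[, 1] +
                          rnorm(nrow(A), 0, 0.2)
                      })
    folds <- assign_folds(500, 2, seed = s)
    param <- mixtree:::subset_dataset(d, fold_param_idx(folds, 1))
    est <- mixtree:::subset_dataset(d, fold_est_idx(folds, 1))
    nu <- fit_nuisance(param, rule, est, w_library = lib_lin(), seed = s)
    nu$g1 <- rep(p_true, length(nu$g1))  # g fixed at the known truth
    r <- target_ate(nu, evaluate_rule(rule, est), est$outcome)$result
    err[s] <- r$psi - 5
    cover[s] <- r$ci_lower <= 5 && 5 <= r$ci_upper
  }
  mc_se <- sd(err) / sqrt(reps)
  expect_lt(abs(mean(err)), 3 * mc_se)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("fold orchestration returns the documented statuses", {
  # strong signal: fold finds a rule and a result
  cfg <- preset_config("interaction-2d", n = 400, seed = 51)
  sim <- simulate_mixtures(cfg)
  folds <- assign_folds(400, 4, seed = 51)
  fr <- run_fold(sim$data, folds, 1, fast_config(51, V = 4))
  expect_equal(fr$status, "ok")
  expect_s3_class(fr$rule, "mixture_rule")
  expect_s3_class(fr$result, "ate_result")
  expect_equal(fr$result$n_effective, length(fold_est_idx(folds, 1)))

  # dropped folds contribute nothing to pooling
  dropped <- list(status = "dropped", rule = fr$rule, result = NULL,
                  nuisance = NULL, v = 2)
  pooled <- pool_folds(list(fr, dropped), sim$data, folds, fast_config(51, V = 4))
  expect_equal(pooled$n_effective, length(fold_est_idx(folds, 1)))
  expect_error(pool_folds(list(dropped), sim$data, folds, fast_config(51)),
               "no pooled result")
})

test_that("pooling over stacked folds tightens the standard error", {
  cfg <- preset_config("interaction-2d", n = 400, seed = 61)
  sim <- simulate_mixtures(cfg)
  res <- mixtree(sim$data, fast_config(61, V = 4))
  ses <- vapply(Filter(function(f) f$status == "ok", res$fold_results),
                function(f) f$result$se, 0)
  expect_lte(res$pooled$se, max(ses))
  expect_equal(res$pooled$n_effective, 400L)
})

test_that("component contrasts exclude intermediate levels", {
  # two well-separated steps => harmonized levels 1..3; the level-2 contrast
  # must use only reference + level-2 rows, so n_effective < n
  d <- make_dataset(n = 600, p = 2, q = 1, seed = 71,
                    y_fun = function(A, W) {
                      2.5 * (A[, 1] > 0.5) + 2.5 * (A[, 1] > 1) + W[, 1] +
                        rnorm(nrow(A), 0, 0.15)
                    })
  folds <- assign_folds(600, 3, seed = 71)
  res <- component_ates(d, folds, "a1", fast_config(71, V = 3))
  cps <- attr(res, "cutpoints")
  expect_gte(length(cps), 2L)
  expect_gte(length(res), 2L)
  expect_true(all(vapply(res, function(r) r$n_effective, 0L) < 600L))
})

test_that("a simulated step effect is recovered by the component ATE", {
  hits <- 0L; reps <- 10L
  for (s in seq_len(reps)) {
    d <- make_dataset(n = 500, p = 2, q = 2, seed = 8000 + s,
                      y_fun = function(A, W) {
                        3 * (A[, 1] > 1) + rnorm(nrow(A), 0, 0.2)
                      })
    folds <- assign_folds(500, 3, seed = s)
    res <- component_ates(d, folds, "a1", fast_config(s, V = 3))
    if (length(res) >= 1L) {
      psis <- vapply(res, function(r) r$psi, 0)
      if (any(abs(psis - 3) <= 0.5)) hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.9)
})

test_that("the full run is deterministic and structurally complete", {
  cfg <- preset_config("interaction-2d", n = 300, seed = 81)
  sim <- simulate_mixtures(cfg)
  conf <- fast_config(81, V = 3, do_components = TRUE)
  r1 <- mixtree(sim$data, conf)
  r2 <- mixtree(sim$data, conf)
  expect_length(r1$fold_results, 3L)
  expect_s3_class(r1$pooled, "ate_result")
  expect_identical(mixtree:::result_rows(r1), mixtree:::result_rows(r2))
})
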