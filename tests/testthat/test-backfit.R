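# heavier simulation checks use the fast learner library (truth is linear in W)
# and modest replicate counts so the suite stays inside its time budget.

test_that("no exposure signal yields a root-only tree in almost all replicates", {
  hits <- 0L
  reps <- 20L
  for (s in seq_len(reps)) {
    d <- make_dataset(n = 500, p = 3, q = 2, seed = 1000 + s,
                      y_fun = function(A, W) W[, 1] + rnorm(nrow(A)))
    m <- iterative_backfit(d, w_library = lib_fast(), seed = s)
    hits <- hits + m$no_rule
  }
  expect_gte(hits / reps, 0.9)
})

test_that("a strong step effect recovers the split location", {
  ok <- 0L
  reps <- 20L
  for (s in seq_len(reps)) {
    d <- make_dataset(n = 500, p = 3, q = 2, seed = 2000 + s,
                      y_fun = function(A, W) {
                        5 * (A[, 1] > 0.5) + W[, 1] + rnorm(nrow(A), 0, 0.1)
                      })
    m <- iterative_backfit(d, w_library = lib_fast(), seed = s)
    if (!m$no_rule) {
      tr <- m$f_fit$tree
      root_var <- m$f_vars[tr$feature[1] + 1L]
      if (root_var == "a1" && abs(tr$threshold[1] - 0.5) <= 0.1) ok <- ok + 1L
    }
  }
  expect_gte(ok / reps, 0.9)
})

test_that("backfitting reports its convergence contract and a monotone risk trace", {
  d <- make_dataset(n = 200, p = 2, q = 2, seed = 11,
                    y_fun = function(A, W) {
                      3 * (A[, 1] > 0.7) + W[, 1] - 0.5 * W[, 2] +
                        rnorm(nrow(A), 0, 0.2)
                    })
  m <- iterative_backfit(d, w_library = lib_fast(), seed = 2)
  expect_equal(length(m$risk_trace), m$n_iterations)
  expect_true(m$converged)
  expect_true(all(diff(m$risk_trace) <= 1e-6))
  expect_lte(m$n_iterations, 10L)

  expect_error(iterative_backfit(make_dataset(n = 20, seed = 1)),
               "sample too small")
})

test_that("extracted leaf rules reconstruct paths and partition the sample", {
  # hand-built depth-2 tree: root split a1 <= 0.3, right child split a1 <= 0.6
  # => right-right leaf path (a1 > 0.3) then (a1 > 0.6) merges to a1 > 0.6
  tree <- list(feature = c(0L, -1L, 0L, -1L, -1L),
               threshold = c(0.3, 0, 0.6, 0, 0),
               left = c(1L, -1L, 3L, -1L, -1L),
               right = c(2L, -1L, 4L, -1L, -1L),
               pred = c(0, 0, 0, 1, 5), n = c(10L, 4L, 6L, 3L, 3L),
               depth = c(0L, 1L, 1L, 2L, 2L))
  model <- structure(
    list(f_fit = list(tree = tree), f_vars = c("a1", "a2"), no_rule = FALSE,
         partial_residual = rep(0, 10), min_support = 0, n = 10),
    class = "backfit_model"
  )
  d <- make_dataset(n = 30, p = 2, q = 0, seed = 3,
                    y_fun = function(A, W) rep(0, nrow(A)))
  rules <- extract_rules(model, d)
  expect_length(rules, 3L)
  descs <- vapply(rules, function(r) r$description, character(1))
  expect_true("a1 <= 0.3" %in% descs)
  expect_true("a1 > 0.3 & a1 <= 0.6" %in% descs)
  expect_true("a1 > 0.6" %in% descs)
  # designated: largest |leaf pred - mean partial residual| = the pred-5 leaf
  expect_equal(attr(rules, "designated"), which(descs == "a1 > 0.6"))

  # property: extracted rules partition the training sample, on fitted trees
  for (s in 1:10) {
    d <- make_dataset(n = 300, p = 3, q = 2, seed = 3000 + s,
                      y_fun = function(A, W) {
                        4 * (A[, 1] > 0.5) * (A[, 2] > 0.5) - 2 * (A[, 3] > 1) +
                          W[, 1] + rnorm(nrow(A), 0, 0.3)
                      })
    m <- iterative_backfit(d, w_library = lib_fast(), seed = s)
    if (m$no_rule) next
    rl <- extract_rules(m, d)
    inds <- vapply(rl, evaluate_rule, integer(length(d$outcome)), data = d)
    expect_equal(unname(rowSums(inds)), rep(1, length(d$outcome)))
  }
})

test_that("root-only models yield no rules and no designated rule", {
  d <- make_dataset(n = 100, p = 2, q = 1, seed = 8,
                    y_fun = function(A, W) rnorm(nrow(A)))
  m <- iterative_backfit(d, w_library = lib_lin(), seed = 3,
                         grid = tree_grid(max_depths = integer(0)))
  expect_true(m$no_rule)
  rules <- extract_rules(m, d)
  expect_length(rules, 0L)
  expect_true(is.na(attr(rules, "designated")))
})

test_that("component thresholds recover a single true cutpoint", {
  ok <- 0L; reps <- 15L
  for (s in seq_len(reps)) {
    d <- make_dataset(n = 500, p = 3, q = 2, seed = 4000 + s,
                      y_fun = function(A, W) {
                        3 * (A[, 1] > 1) + W[, 1] + rnorm(nrow(A), 0, 0.2)
                      })
    ct <- component_thresholds(d, "a1", w_library = lib_fast(), seed = s)
    if (length(ct$cutpoints) == 1 && abs(ct$cutpoints - 1) <= 0.15) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.9)
})

test_that("no-signal components come back empty", {
  empty <- 0L; reps <- 15L
  for (s in seq_len(reps)) {
    d <- make_dataset(n = 400, p = 2, q = 2, seed = 5000 + s,
                      y_fun = function(A, W) W[, 1] + rnorm(nrow(A)))
    ct <- component_thresholds(d, "a1", w_library = lib_fast(), seed = s)
    empty <- empty + ct$empty
  }
  expect_gte(empty / reps, 0.9)
})

test_that("threshold levels tile the line with the lowest level as reference", {
  d <- make_dataset(n = 500, p = 2, q = 1, seed = 21,
                    y_fun = function(A, W) {
                      2 * (A[, 1] > 0.5) + 3 * (A[, 1] > 1) + W[, 1] +
                        rnorm(nrow(A), 0, 0.15)
                    })
  ct <- component_thresholds(d, "a1", w_library = lib_fast(), seed = 4)
  expect_false(ct$empty)
  k <- length(ct$cutpoints)
  expect_length(ct$levels, k + 1L)
  expect_identical(ct$reference$description, ct$levels[[1]]$description)
  # consecutive levels share a boundary; ends are infinite
  expect_equal(ct$levels[[1]]$predicates$lower, -Inf)
  expect_equal(ct$levels[[k + 1]]$predicates$upper, Inf)
  for (j in seq_len(k)) {
    expect_equal(ct$levels[[j]]$predicates$upper,
                 ct$levels[[j + 1]]$predicates$lower)
  }
  # membership indicators partition the sample
  inds <- vapply(ct$levels, evaluate_rule, integer(length(d$outcome)), data = d)
  expect_equal(unname(rowSums(inds)), rep(1, length(d$outcome)))
})

test_that("fitted values approach the truth as n grows (additive model)", {
  mse_at <- function(n, seed) {
    d <- make_dataset(n = n, p = 2, q = 2, seed = seed,
                      y_fun = function(A, W) {
                        3 * (A[, 1] > 0.8) + W[, 1] + 0.5 * W[, 2] +
                          rnorm(nrow(A), 0, 0.3)
                      })
    truth <- 3 * (d$exposures[, 1] > 0.8) + d$covariates[, 1] +
      0.5 * d$covariates[, 2]
    m <- iterative_backfit(d, w_library = lib_fast(), seed = seed)
    mean((m$fhat + m$hhat - truth)^2)
  }
  m200 <- mean(vapply(1:3, function(s) mse_at(200, 6000 + s), 0))
  m1000 <- mean(vapply(1:3, function(s) mse_at(1000, 6000 + s), 0))
  expect_lt(m1000, m200)
})
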