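test_that("fold assignment is a balanced, reproducible partition", {
  # n = V: labels are a permutation, every estimation sample is a singleton
  f <- assign_folds(10, 10, seed = 4)
  expect_setequal(f$labels, 1:10)

  # balance: multiset of sizes for n = 7, V = 3 is {3, 2, 2}
  f <- assign_folds(7, 3, seed = 99)
  expect_equal(sort(tabulate(f$labels, 3)), c(2, 2, 3))

  # determinism under a fixed seed
  expect_identical(assign_folds(100, 10, seed = 1)$labels,
                   assign_folds(100, 10, seed = 1)$labels)

  # property: partition + balance for random (n, V)
  for (s in 1:25) {
    set.seed(s)
    n <- sample(10:200, 1)
    V <- sample(2:min(10, n), 1)
    f <- assign_folds(n, V, seed = s)
    sizes <- tabulate(f$labels, V)
    expect_equal(sum(sizes), n)
    expect_true(all(sizes >= 1))
    expect_lte(max(sizes) - min(sizes), 1)
    # every observation lies in exactly one estimation sample
    expect_equal(sort(unlist(lapply(1:V, function(v) fold_est_idx(f, v)))),
                 seq_len(n))
  }
})

test_that("fold assignment rejects invalid V", {
  expect_error(assign_folds(10, 1, seed = 1), "invalid fold count")
  expect_error(assign_folds(10, 11, seed = 1), "invalid fold count")
})

test_that("dataset construction validates, drops incomplete rows and encodes factors", {
  df_a <- data.frame(a1 = c(1, 2, 3, NA, 5), a2 = c(0.1, 0.2, 0.3, 0.4, 0.5))
  df_w <- data.frame(w1 = c(1, 2, 3, 4, 5),
                     grp = c("x", "y", "z", "x", "y"))
  y <- c(1, 2, 3, 4, 5)
  d <- mixture_dataset(df_a, df_w, y)
  expect_equal(d$n_dropped, 1L)
  expect_equal(length(d$outcome), 4L)
  # one-hot (drop-first) coding for the 3-level factor
  expect_true(all(c("grp_y", "grp_z") %in% colnames(d$covariates)))
  expect_equal(ncol(d$covariates), 3L)
  expect_equal(d$encoding$grp, c("x", "y", "z"))

  expect_error(mixture_dataset(data.frame(a1 = letters[1:3]), NULL, 1:3),
               "not numeric")
  expect_error(mixture_dataset(data.frame(a1 = rep(1, 3)), NULL, 1:3),
               "fewer than 2 distinct")
  expect_equal(mixture_dataset(df_a[1:3, ], NULL, c(0, 1, 0))$outcome_type,
               "binary")
})

test_that("rule evaluation follows the half-open convention", {
  d <- mixture_dataset(data.frame(x1 = c(1, 2, 3, 5, 6)), NULL, rep(0, 5))
  # vacuous predicate covers everything
  expect_equal(evaluate_rule(mixture_rule("x1", -Inf, Inf), d), rep(1L, 5))
  # (2, 5]: strictly above 2, up to and including 5
  expect_equal(evaluate_rule(mixture_rule("x1", 2, 5), d), c(0L, 0L, 1L, 1L, 0L))
  expect_error(evaluate_rule(mixture_rule("nope", 0, 1), d), "nope")
})

test_that("rule evaluation matches the brute-force row oracle", {
  for (s in 1:1000) {
    d <- make_dataset(n = 20, p = 3, q = 0, seed = s,
                      y_fun = function(A, W) rep(0, nrow(A)))
    r <- random_rule(d, seed = s + 5000)
    expect_identical(evaluate_rule(r, d), brute_force_indicator(r, d))
  }
})

test_that("rule construction merges predicates per variable", {
  r <- mixture_rule(c("a1", "a1"), c(0.3, 0.6), c(Inf, Inf))
  expect_equal(nrow(r$predicates), 1L)
  expect_equal(r$predicates$lower, 0.6)
  expect_error(mixture_rule(c("a1", "a1"), c(2, -Inf), c(Inf, 1)),
               "empty interval")
})

test_that("rule union behaves as a disjunction", {
  d <- mixture_dataset(data.frame(x1 = c(0.5, 1.5, 3)), NULL, rep(0, 3))
  r1 <- mixture_rule("x1", 0, 1)
  r2 <- mixture_rule("x1", 1, 2)
  expect_equal(rule_union(list(r1), d)$indicator, evaluate_rule(r1, d))
  expect_equal(rule_union(list(r1, r1), d)$indicator, evaluate_rule(r1, d))
  expect_equal(rule_union(list(r1, r2), d)$indicator, c(1L, 1L, 0L))
  expect_error(rule_union(list(), d), "at least one")
})

test_that("rule serialization round-trips", {
  r <- parse_rule("x1 > 2 & x1 <= 5")
  expect_equal(r$predicates$lower, 2)
  expect_equal(r$predicates$upper, 5)

  expect_error(parse_rule("x1 >"), "clause 1")
  expect_error(parse_rule("x1 > 2 & bad-var < 3"), "clause 2")

  # property: parse . serialize is the identity on random rules
  d <- make_dataset(n = 10, p = 4, q = 0, seed = 1,
                    y_fun = function(A, W) rep(0, nrow(A)))
  for (s in 1:200) {
    r <- random_rule(d, seed = s)
    r2 <- parse_rule(serialize_rule(r))
    expect_equal(r2$predicates[order(r2$predicates$var), ],
                 r$predicates[order(r$predicates$var), ],
                 ignore_attr = TRUE)
    expect_identical(serialize_rule(r2), serialize_rule(r))
  }
})
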