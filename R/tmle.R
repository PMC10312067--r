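#' Method configuration
#'
#' Collects every tunable the estimator exposes.  Defaults follow the
#' package's stated world: V = 5 outer folds, tree depths 1-3, minimum leaf
#' fractions 0.05/0.1, backfit tolerance `1e-3 * sd(Y)` with at most 10
#' iterations, designated-rule support floor 0.05, propensity truncation at
#' (0.025, 0.975).
#'
#' @param V outer folds.
#' @param seed integer seed; mandatory — no unseeded runs.
#' @param tree_max_depths,tree_min_leaf_fracs tree grid, see [tree_grid()].
#' @param backfit_tol,backfit_max_iter backfitting controls
#'   (see [iterative_backfit()]).
#' @param min_support designated-rule leaf support floor (fraction of n).
#' @param g_bounds propensity truncation bounds.
#' @param w_library learner library for all nuisance regressions.
#' @param do_components also run the per-component threshold analysis.
#' @return A list of class `mixtree_config`.
#' @export
mixtree_config <- function(V = 5L, seed = 1L,
                           tree_max_depths = c(1L, 2L, 3L),
                           tree_min_leaf_fracs = c(0.05, 0.1),
                           backfit_tol = NULL, backfit_max_iter = 10L,
                           min_support = 0.05, g_bounds = c(0.025, 0.975),
                           w_library = default_library(),
                           do_components = TRUE) {
  if (V < 2L) stop("V must be at least 2")
  if (length(g_bounds) != 2L || g_bounds[1] <= 0 || g_bounds[2] >= 1 ||
      g_bounds[1] >= g_bounds[2]) {
    stop("g_bounds must satisfy 0 < lower < upper < 1")
  }
  structure(
    list(V = as.integer(V), seed = as.integer(seed),
         tree_max_depths = as.integer(tree_max_depths),
         tree_min_leaf_fracs = tree_min_leaf_fracs,
         backfit_tol = backfit_tol, backfit_max_iter = as.integer(backfit_max_iter),
         min_support = min_support, g_bounds = g_bounds,
         w_library = w_library, do_components = isTRUE(do_components)),
    class = "mixtree_config"
  )
}

# Outcome scaling to [0,1] for the bounded-loss logistic fluctuation.  The
# bounds come from the parameter-generating sample with the range widened by
# 10% (5% each side) to reduce clipping of estimation-sample outcomes.
outcome_scale_from <- function(y, outcome_type) {
  if (outcome_type == "binary") return(c(0, 1))
  r <- range(y)
  pad <- 0.05 * (r[2] - r[1])
  if (pad == 0) pad <- 0.5          # degenerate constant outcome
  c(r[1] - pad, r[2] + pad)
}

scale_y <- function(y, sc) clip((y - sc[1]) / (sc[2] - sc[1]), 0, 1)

positivity_error <- function(msg) {
  structure(class = c("mixtree_positivity_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Fit nuisance functions for a fixed rule
#'
#' On the parameter-generating sample, fits (1) the outcome regression
#' `Q(a, W) = E(Y | indicator = a, W)` by a super-learner ensemble with the
#' rule indicator as a feature, and (2) the propensity `g(W) = P(indicator = 1
#' | W)`.  Both are then predicted on the estimation sample — the outcome
#' regression at the indicator forced to 0 and to 1 — and the propensity is
#' truncated to `g_bounds`.  A continuous outcome is scaled to `[0, 1]` using
#' bounds from the parameter-generating sample (range widened 10%).
#'
#' @param param_sample,est_sample [mixture_dataset()]s (the rule must be
#'   evaluable on both).
#' @param rule a [mixture_rule()].
#' @param w_library learner library.
#' @param g_bounds propensity truncation bounds.
#' @param seed integer seed.
#' @param outcome_scale optional fixed `(min, max)` scaling pair; used by the
#'   pooled estimator so every fold shares one scale.
#' @return Object of class `nuisance_fit`: `Q0`, `Q1`, `g1` (estimation-sample
#'   vectors), `g_bounds`, `outcome_scale`, plus the fitted models.  Raises a
#'   positivity error (condition class `mixtree_positivity_error`) when either
#'   indicator class has fewer than 5 parameter-generating observations.
#' @export
fit_nuisance <- function(param_sample, rule, est_sample,
                         w_library = default_library(),
                         g_bounds = c(0.025, 0.975), seed = 1L,
                         outcome_scale = NULL) {
  a_param <- evaluate_rule(rule, param_sample)
  if (sum(a_param == 1) < 5L || sum(a_param == 0) < 5L) {
    stop(positivity_error(sprintf(
      "positivity failure: rule '%s' leaves %d exposed / %d unexposed in the parameter-generating sample",
      rule$description, sum(a_param == 1), sum(a_param == 0))))
  }
  sc <- outcome_scale %||% outcome_scale_from(param_sample$outcome,
                                              param_sample$outcome_type)
  y_param <- scale_y(param_sample$outcome, sc)
  W_param <- param_sample$covariates
  W_est <- est_sample$covariates

  q_loss <- if (param_sample$outcome_type == "binary") "nll" else "se"
  Q_fit <- fit_ensemble(cbind(ind = a_param, W_param), y_param,
                        library = w_library, inner_V = 5L, loss = q_loss,
                        seed = seed + 211L)
  m <- n_obs(est_sample)
  Q0 <- clip(predict(Q_fit, cbind(ind = rep(0, m), W_est)), .PROB_EPS, 1 - .PROB_EPS)
  Q1 <- clip(predict(Q_fit, cbind(ind = rep(1, m), W_est)), .PROB_EPS, 1 - .PROB_EPS)

  g_fit <- if (ncol(W_param) == 0L) {
    NULL
  } else {
    fit_ensemble(W_param, a_param, library = w_library, inner_V = 5L,
                 loss = "nll", seed = seed + 409L)
  }
  g1 <- if (is.null(g_fit)) rep(mean(a_param), m) else predict(g_fit, W_est)
  g1 <- clip(g1, g_bounds[1], g_bounds[2])

  structure(
    list(Q0 = Q0, Q1 = Q1, g1 = g1, g_bounds = g_bounds, outcome_scale = sc,
         Q_fit = Q_fit, g_fit = g_fit,
         outcome_type = param_sample$outcome_type),
    class = "nuisance_fit"
  )
}

# Solve the fluctuation score equation sum_i H_i (y_i - expit(logit(Qa_i) +
# eps * H_i)) = 0 by safeguarded Newton (the score is strictly decreasing in
# eps, so the root is unique when it exists).  Falls back to golden-section
# maximization of the binomial log-likelihood if Newton leaves [-20, 20].
solve_epsilon <- function(H, offset, y) {
  score <- function(e) sum(H * (y - expit(offset + e * H)))
  eps <- 0
  for (it in 1:100) {
    p <- expit(offset + eps * H)
    s <- sum(H * (y - p))
    if (abs(s) < 1e-12 * length(y)) break
    d <- -sum(H^2 * p * (1 - p))
    if (!is.finite(d) || d >= -1e-300) break
    step <- -s / d
    step <- clip(step, -2, 2)              # damp wild early steps
    eps_new <- eps + step
    # backtrack until |score| decreases
    for (half in 1:30) {
      if (abs(score(eps_new)) <= abs(s) || abs(eps_new - eps) < 1e-15) break
      eps_new <- (eps + eps_new) / 2
    }
    if (abs(eps_new - eps) < 1e-14) { eps <- eps_new; break }
    eps <- eps_new
    if (abs(eps) > 20) break
  }
  if (!is.finite(eps) || abs(eps) > 20) {
    ll <- function(e) {
      p <- clip(expit(offset + e * H), 1e-12, 1 - 1e-12)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    }
    eps <- optimize(ll, c(-20, 20), tol = 1e-12)$minimum
  }
  eps
}

#' TMLE targeting step for the ATE of rule membership
#'
#' Applies the one-dimensional logistic fluctuation with clever covariate
#' `H(a, w) = a / g1(w) - (1 - a) / (1 - g1(w))`: `epsilon` maximizes the
#' binomial log-likelihood of the scaled outcome on `H` with offset
#' `logit(Q(a, w))`, the counterfactual predictions are updated to
#' `Q*0 = expit(logit(Q0) - eps / (1 - g1))` and
#' `Q*1 = expit(logit(Q1) + eps / g1)`, and the ATE, efficient influence
#' curve, standard error and 95% normal CI are computed on the original
#' outcome scale.  After targeting the empirical mean of the EIC is zero to
#' numerical precision (the fluctuation solves the score equation).
#'
#' @param nuisance a `nuisance_fit` for the estimation sample.
#' @param indicator 0/1 rule membership on the estimation sample.
#' @param y outcome on the estimation sample, on the original scale.
#' @param rule_description text recorded on the result.
#' @param scope label such as `"fold 3"`, `"pooled-mixture"`, or a component
#'   level tag.
#' @return List with `epsilon` and `result`, an `ate_result`: `psi`, `se`,
#'   `ci_lower`, `ci_upper`, per-observation `eic`, `rule_description`,
#'   `scope`, `n_effective`.
#' @export
target_ate <- function(nuisance, indicator, y, rule_description = "",
                       scope = "fold") {
  m <- length(y)
  if (m < 10L) stop("estimation sample too small for targeting (m < 10)")
  if (length(indicator) != m || length(nuisance$Q0) != m) {
    stop("indicator, outcome and nuisance predictions must have equal length")
  }
  sc <- nuisance$outcome_scale
  y_scaled <- scale_y(y, sc)
  g1 <- nuisance$g1
  Q0 <- nuisance$Q0
  Q1 <- nuisance$Q1
  H <- indicator / g1 - (1 - indicator) / (1 - g1)
  QA <- ifelse(indicator == 1, Q1, Q0)
  offset <- logit(QA)

  eps <- tryCatch(solve_epsilon(H, offset, y_scaled), error = function(e) NA_real_)
  if (!is.finite(eps)) {
    warning("fluctuation likelihood was non-finite; epsilon set to 0")
    eps <- 0
  }
  Q0s <- expit(logit(Q0) - eps / (1 - g1))
  Q1s <- expit(logit(Q1) + eps / g1)
  QAs <- ifelse(indicator == 1, Q1s, Q0s)

  range_y <- sc[2] - sc[1]
  psi_scaled <- mean(Q1s - Q0s)
  psi <- psi_scaled * range_y
  # EIC on the original outcome scale; the location shift cancels throughout
  eic <- range_y * (H * (y_scaled - QAs) + (Q1s - Q0s) - psi_scaled)
  se <- sd(eic) / sqrt(m)
  result <- structure(
    list(psi = psi, se = se,
         ci_lower = psi - 1.96 * se, ci_upper = psi + 1.96 * se,
         eic = eic, rule_description = rule_description, scope = scope,
         n_effective = m, epsilon = eps),
    class = "ate_result"
  )
  list(epsilon = eps, result = result)
}

#' @export
print.ate_result <- function(x, ...) {
  cat(sprintf("<ate_result> [%s] psi = %.4f (se %.4f, 95%% CI %.4f..%.4f, n = %d)\n",
              x$scope, x$psi, x$se, x$ci_lower, x$ci_upper, x$n_effective))
  if (nzchar(x$rule_description)) cat("  rule:", x$rule_description, "\n")
  invisible(x)
}

#' Run one cross-validation fold
#'
#' On fold `v`: backfit on the parameter-generating sample, extract the
#' designated rule, fit nuisances there, then evaluate the rule and target the
#' ATE on the estimation sample.  A root-only tree is a first-class "no rule"
#' outcome; a positivity failure drops the fold with a warning.
#'
#' @param data a [mixture_dataset()].
#' @param folds a `fold_assignment` on the same n.
#' @param v fold index in `1..V`.
#' @param config a [mixtree_config()].
#' @return List with `status` (`"ok"`, `"no_rule"` or `"dropped"`), `rule`
#'   (or `NULL`), `result` (or `NULL`), and the fold's `nuisance` fit.
#' @export
run_fold <- function(data, folds, v, config = mixtree_config()) {
  stopifnot(v >= 1L, v <= folds$V)
  pidx <- fold_param_idx(folds, v)
  eidx <- fold_est_idx(folds, v)
  param <- subset_dataset(data, pidx)
  est <- subset_dataset(data, eidx)

  model <- iterative_backfit(
    param,
    grid = tree_grid(config$tree_max_depths, config$tree_min_leaf_fracs),
    w_library = config$w_library, tol = config$backfit_tol,
    max_iter = config$backfit_max_iter, seed = config$seed + 31L * v,
    min_support = config$min_support
  )
  rules <- extract_rules(model, param)
  des <- attr(rules, "designated")
  if (!length(rules) || is.na(des)) {
    return(list(status = "no_rule", rule = NULL, result = NULL, nuisance = NULL,
                model = model, v = v))
  }
  rule <- rules[[des]]
  rule$provenance <- sprintf("fold %d", v)

  nuis <- tryCatch(
    fit_nuisance(param, rule, est, w_library = config$w_library,
                 g_bounds = config$g_bounds, seed = config$seed + 101L * v),
    mixtree_positivity_error = function(e) {
      warning(sprintf("fold %d dropped: %s", v, conditionMessage(e)), call. = FALSE)
      NULL
    }
  )
  if (is.null(nuis)) {
    return(list(status = "dropped", rule = rule, result = NULL, nuisance = NULL,
                model = model, v = v))
  }
  ind_est <- evaluate_rule(rule, est)
  tg <- target_ate(nuis, ind_est, est$outcome,
                   rule_description = rule$description,
                   scope = sprintf("fold %d", v))
  list(status = "ok", rule = rule, result = tg$result, nuisance = nuis,
       model = model, v = v)
}

#' Pool fold-specific results via the union rule
#'
#' The pooled estimand is the ATE of membership in the union of the
#' fold-specific rules.  For every contributing fold the nuisance models are
#' refit on that fold's parameter-generating sample with the union-rule
#' indicator (sharing one outcome scale across folds), predicted on the
#' estimation sample, and the estimation-sample rows are stacked.  A single
#' fluctuation `epsilon` is then fit on the stack and `psi`/`se` come from the
#' stacked efficient influence curve.
#'
#' @param fold_results list as returned by [run_fold()].
#' @param data,folds the full dataset and its fold assignment.
#' @param config a [mixtree_config()].
#' @return An `ate_result` with scope `"pooled-mixture"` plus attribute
#'   `union_description`.
#' @export
pool_folds <- function(fold_results, data, folds, config = mixtree_config()) {
  ok <- Filter(function(f) f$status == "ok", fold_results)
  if (!length(ok)) stop("no pooled result: every fold was dropped or found no rule")
  union <- rule_union(lapply(ok, `[[`, "rule"), data)
  union_rule <- parse_union_for_eval(lapply(ok, `[[`, "rule"))
  sc <- outcome_scale_from(data$outcome, data$outcome_type)

  stack <- list(Q0 = numeric(0), Q1 = numeric(0), g1 = numeric(0),
                ind = integer(0), y = numeric(0))
  for (f in ok) {
    pidx <- fold_param_idx(folds, f$v)
    eidx <- fold_est_idx(folds, f$v)
    param <- subset_dataset(data, pidx)
    est <- subset_dataset(data, eidx)
    nu <- tryCatch(
      fit_nuisance_union(param, union_rule, est, config, sc,
                         seed = config$seed + 101L * f$v + 3L),
      mixtree_positivity_error = function(e) {
        warning(sprintf("fold %d excluded from pooling: %s", f$v,
                        conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    if (is.null(nu)) next
    stack$Q0 <- c(stack$Q0, nu$Q0)
    stack$Q1 <- c(stack$Q1, nu$Q1)
    stack$g1 <- c(stack$g1, nu$g1)
    stack$ind <- c(stack$ind, nu$ind)
    stack$y <- c(stack$y, est$outcome)
  }
  if (!length(stack$y)) stop("no pooled result: pooling excluded every fold")

  nuis <- structure(
    list(Q0 = stack$Q0, Q1 = stack$Q1, g1 = stack$g1,
         g_bounds = config$g_bounds, outcome_scale = sc,
         outcome_type = data$outcome_type),
    class = "nuisance_fit"
  )
  tg <- target_ate(nuis, stack$ind, stack$y,
                   rule_description = union$description, scope = "pooled-mixture")
  res <- tg$result
  attr(res, "union_description") <- union$description
  res
}

# The union of half-open-interval conjunctions is not itself a conjunction, so
# carry the member rules and evaluate the disjunction directly.
parse_union_for_eval <- function(rules) {
  structure(list(rules = rules), class = "mixtree_rule_union")
}

evaluate_any <- function(rule_or_union, data) {
  if (inherits(rule_or_union, "mixtree_rule_union")) {
    rule_union(rule_or_union$rules, data)$indicator
  } else {
    evaluate_rule(rule_or_union, data)
  }
}

# fit_nuisance for either a single rule or a union-of-rules indicator, with an
# externally fixed outcome scale; returns estimation-sample predictions plus
# the indicator.
fit_nuisance_union <- function(param, rule_or_union, est, config, sc, seed) {
  a_param <- evaluate_any(rule_or_union, param)
  if (sum(a_param == 1) < 5L || sum(a_param == 0) < 5L) {
    stop(positivity_error(sprintf(
      "union rule leaves %d exposed / %d unexposed in the parameter-generating sample",
      sum(a_param == 1), sum(a_param == 0))))
  }
  y_param <- scale_y(param$outcome, sc)
  q_loss <- if (param$outcome_type == "binary") "nll" else "se"
  Q_fit <- fit_ensemble(cbind(ind = a_param, param$covariates), y_param,
                        library = config$w_library, inner_V = 5L, loss = q_loss,
                        seed = seed + 211L)
  m <- n_obs(est)
  Q0 <- clip(predict(Q_fit, cbind(ind = rep(0, m), est$covariates)),
             .PROB_EPS, 1 - .PROB_EPS)
  Q1 <- clip(predict(Q_fit, cbind(ind = rep(1, m), est$covariates)),
             .PROB_EPS, 1 - .PROB_EPS)
  g1 <- if (ncol(param$covariates) == 0L) {
    rep(mean(a_param), m)
  } else {
    predict(fit_ensemble(param$covariates, a_param, library = config$w_library,
                         inner_V = 5L, loss = "nll", seed = seed + 409L),
            est$covariates)
  }
  g1 <- clip(g1, config$g_bounds[1], config$g_bounds[2])
  list(Q0 = Q0, Q1 = Q1, g1 = g1, ind = evaluate_any(rule_or_union, est))
}

#' Per-component threshold ATEs
#'
#' For one exposure variable: per fold, data-adaptive cutpoints are found on
#' the parameter-generating sample ([component_thresholds()]); cutpoints are
#' harmonized across folds by their union; for each non-reference level `L`
#' the treatment indicator is membership in `L` and the comparison set is the
#' *reference (lowest) level only* — rows in other levels are excluded from
#' that contrast.  Nuisances are fit per fold on the restricted
#' parameter-generating sample, estimation-sample rows are stacked and a
#' single fluctuation per level yields one pooled `ate_result` per level.
#'
#' @param data a [mixture_dataset()].
#' @param folds a `fold_assignment`.
#' @param variable exposure column name.
#' @param config a [mixtree_config()].
#' @return List of `ate_result`s (one per harmonized non-reference level;
#'   empty when no fold finds a cutpoint), with attribute `cutpoints`.
#' @export
component_ates <- function(data, folds, variable, config = mixtree_config()) {
  per_fold <- lapply(seq_len(folds$V), function(v) {
    param <- subset_dataset(data, fold_param_idx(folds, v))
    component_thresholds(param, variable, w_library = config$w_library,
                         seed = config$seed + 977L * v,
                         max_depths = config$tree_max_depths,
                         tol = config$backfit_tol,
                         max_iter = config$backfit_max_iter,
                         min_support = config$min_support)
  })
  cutpoints <- sort(unique(unlist(lapply(per_fold, `[[`, "cutpoints"))))
  if (!length(cutpoints)) {
    out <- list()
    attr(out, "cutpoints") <- numeric(0)
    return(out)
  }
  bounds <- c(-Inf, cutpoints, Inf)
  n_lev <- length(bounds) - 1L
  sc <- outcome_scale_from(data$outcome, data$outcome_type)
  a <- data$exposures[, variable]
  level_of <- findInterval(a, cutpoints, left.open = TRUE) + 1L  # a <= c1 -> level 1

  results <- list()
  for (lev in 2:n_lev) {
    stack <- list(Q0 = numeric(0), Q1 = numeric(0), g1 = numeric(0),
                  ind = integer(0), y = numeric(0))
    for (v in seq_len(folds$V)) {
      pidx <- fold_param_idx(folds, v)
      eidx <- fold_est_idx(folds, v)
      pkeep <- pidx[level_of[pidx] %in% c(1L, lev)]
      ekeep <- eidx[level_of[eidx] %in% c(1L, lev)]
      if (sum(level_of[pkeep] == lev) < 5L || sum(level_of[pkeep] == 1L) < 5L ||
          length(ekeep) < 2L) {
        next
      }
      param <- subset_dataset(data, pkeep)
      est <- subset_dataset(data, ekeep)
      lev_rule <- mixture_rule(variable, bounds[lev], bounds[lev + 1L])
      nu <- tryCatch(
        fit_nuisance_union(param, lev_rule, est, config, sc,
                           seed = config$seed + 977L * v + 11L * lev),
        mixtree_positivity_error = function(e) NULL
      )
      if (is.null(nu)) next
      stack$Q0 <- c(stack$Q0, nu$Q0)
      stack$Q1 <- c(stack$Q1, nu$Q1)
      stack$g1 <- c(stack$g1, nu$g1)
      stack$ind <- c(stack$ind, nu$ind)
      stack$y <- c(stack$y, est$outcome)
    }
    if (length(stack$y) < 10L) next
    nuis <- structure(
      list(Q0 = stack$Q0, Q1 = stack$Q1, g1 = stack$g1,
           g_bounds = config$g_bounds, outcome_scale = sc,
           outcome_type = data$outcome_type),
      class = "nuisance_fit"
    )
    desc <- sprintf("%s in (%s, %s] vs reference (%s, %s]",
                    variable, format(bounds[lev]), format(bounds[lev + 1L]),
                    format(bounds[1L]), format(bounds[2L]))
    tg <- target_ate(nuis, stack$ind, stack$y, rule_description = desc,
                     scope = sprintf("component %s level %d vs reference",
                                     variable, lev))
    results[[length(results) + 1L]] <- tg$result
  }
  attr(results, "cutpoints") <- cutpoints
  results
}

#' Full analysis: rule discovery plus CV-TMLE estimation
#'
#' The orchestrating entry point.  Assigns V folds; per fold discovers the
#' designated mixture rule by iterative backfitting on the
#' parameter-generating sample and targets its ATE on the estimation sample;
#' pools fold results via the union rule; optionally repeats the analysis for
#' each mixture component's data-adaptive thresholds.  "No tree found" is a
#' first-class, non-error outcome.  The whole run is deterministic given
#' `config$seed`.
#'
#' @param data a [mixture_dataset()].
#' @param config a [mixtree_config()].
#' @return Object of class `mixtree_result`: `fold_results` (list per fold),
#'   `pooled` (`ate_result` or `NULL`), `components` (named per exposure),
#'   `rules` (designated fold rules), `diagnostics` (fold statuses, dropped
#'   folds, number of contrasts reported without multiplicity adjustment) and
#'   the `config`.
#' @export
mixtree <- function(data, config = mixtree_config()) {
  stopifnot(inherits(data, "mixture_dataset"))
  folds <- assign_folds(n_obs(data), config$V, config$seed)
  fold_results <- lapply(seq_len(config$V), function(v) {
    run_fold(data, folds, v, config)
  })
  statuses <- vapply(fold_results, `[[`, character(1), "status")
  pooled <- if (any(statuses == "ok")) {
    tryCatch(pool_folds(fold_results, data, folds, config),
             error = function(e) NULL)
  } else {
    NULL
  }
  components <- list()
  if (config$do_components) {
    for (v in colnames(data$exposures)) {
      components[[v]] <- component_ates(data, folds, v, config)
    }
  }
  n_contrasts <- sum(statuses == "ok") + (!is.null(pooled)) +
    sum(vapply(components, length, integer(1)))
  structure(
    list(
      fold_results = fold_results, pooled = pooled, components = components,
      rules = lapply(Filter(function(f) f$status == "ok", fold_results),
                     `[[`, "rule"),
      folds = folds,
      diagnostics = list(
        fold_status = statuses,
        dropped_folds = which(statuses == "dropped"),
        no_rule_folds = which(statuses == "no_rule"),
        n_contrasts = n_contrasts,
        multiplicity_note = sprintf(
          "%d contrasts reported without multiplicity adjustment", n_contrasts)
      ),
      config = config
    ),
    class = "mixtree_result"
  )
}

#' @export
print.mixtree_result <- function(x, ...) {
  cat(sprintf("<mixtree_result> V = %d folds, seed = %d\n",
              x$config$V, x$config$seed))
  for (f in x$fold_results) {
    if (f$status == "ok") {
      print(f$result)
    } else {
      cat(sprintf("  fold %d: %s\n", f$v,
                  if (f$status == "no_rule") "no rule found" else "dropped (positivity)"))
    }
  }
  if (!is.null(x$pooled)) print(x$pooled) else cat("  no pooled mixture result\n")
  for (v in names(x$components)) {
    cps <- attr(x$components[[v]], "cutpoints")
    if (length(cps)) {
      cat(sprintf("  component %s: cutpoints %s\n", v,
                  paste(signif(cps, 5), collapse = ", ")))
      for (r in x$components[[v]]) print(r)
    } else {
      cat(sprintf("  component %s: no cutpoints found\n", v))
    }
  }
  cat(" ", x$diagnostics$multiplicity_note, "\n")
  invisible(x)
}
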