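#' Default tree hyperparameter grid
#'
#' Depths 1-3 crossed with minimum leaf fractions 0.05 and 0.1, plus the
#' root-only (depth 0) model.  The root is a first-class candidate: when no
#' exposure signal exists, the intercept wins the inner cross-validation and
#' the procedure reports "no rule" rather than inventing one.  Shallow depths
#' are deliberate — interpretability and positivity both degrade as leaves
#' shrink.
#'
#' @param max_depths integer vector of tree depths to try.
#' @param min_leaf_fracs numeric vector of minimum leaf fractions.
#' @return data.frame with columns `max_depth`, `min_leaf_frac`, simplest
#'   first (ties in CV risk resolve toward simpler trees).
#' @export
tree_grid <- function(max_depths = c(1L, 2L, 3L), min_leaf_fracs = c(0.05, 0.1)) {
  g <- expand.grid(max_depth = sort(unique(as.integer(max_depths))),
                   min_leaf_frac = sort(unique(min_leaf_fracs), decreasing = TRUE))
  rbind(data.frame(max_depth = 0L, min_leaf_frac = 1), g)
}

# Inner-CV held-out squared errors of a tree grid point fit to (A, r).
# Depth 0 is the cross-validated intercept.
tree_cv_losses <- function(A, r, depth, frac, folds) {
  loss <- numeric(length(r))
  for (v in seq_len(folds$V)) {
    tr <- fold_param_idx(folds, v)
    te <- fold_est_idx(folds, v)
    pred <- if (depth == 0L) {
      rep(mean(r[tr]), length(te))
    } else {
      fit <- cpp_tree_fit(A[tr, , drop = FALSE], r[tr], depth,
                          min_leaf_from_frac(frac, length(tr)))
      cpp_tree_predict(fit, A[te, , drop = FALSE])
    }
    loss[te] <- (r[te] - pred)^2
  }
  loss
}

# Discrete tree selection over the grid by inner-CV risk with the
# one-standard-error rule: among grid points whose CV risk is within one
# standard error of the minimum, take the simplest (lowest depth, then
# largest leaf fraction).  A cross-validated minimiser alone over-selects
# spurious splits under noise; the 1-SE rule is the standard CART remedy and
# is what lets a pure-noise exposure come back "no rule".  Discrete selection
# (not a convex blend) is deliberate: a blended tree ensemble has no single
# rule set to extract.
select_tree <- function(A, r, grid, folds) {
  n <- length(r)
  risks <- numeric(nrow(grid))
  ses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    loss <- tree_cv_losses(A, r, grid$max_depth[g], grid$min_leaf_frac[g], folds)
    risks[g] <- mean(loss)
    ses[g] <- sd(loss) / sqrt(n)
  }
  gmin <- which.min(risks)
  eligible <- which(risks <= risks[gmin] + ses[gmin])
  ord <- eligible[order(grid$max_depth[eligible],
                        -grid$min_leaf_frac[eligible])]
  best <- ord[1]
  depth <- grid$max_depth[best]
  tree <- if (depth == 0L) {
    NULL
  } else {
    cpp_tree_fit(A, r, depth, min_leaf_from_frac(grid$min_leaf_frac[best], length(r)))
  }
  # a grid point may select a tree that degenerates to the root on refit
  no_split <- is.null(tree) || all(tree$feature < 0)
  list(tree = tree, grid_row = best, cv_risk = risks[best],
       cv_risks = risks, no_split = no_split)
}

#' Iterative backfitting of E(Y|A,W) = f(A) + h(W)
#'
#' Alternates between fitting `h` — an unrestricted super-learner ensemble
#' over the covariates — to the partial residual `Y - f(A)`, and fitting `f` —
#' a decision tree over the joint exposures, selected from a hyperparameter
#' grid by inner cross-validated risk — to `Y - h(W)`.  Iteration stops when
#' the maximum absolute change in combined fitted values drops below `tol` or
#' after `max_iter` rounds.  A component update that would *increase* the
#' combined in-sample risk is rejected, so `risk_trace` is non-increasing by
#' construction.
#'
#' @param data a [mixture_dataset()] (the parameter-generating sample);
#'   at least 30 rows.
#' @param grid tree hyperparameter grid from [tree_grid()].
#' @param w_library learner library for `h(W)`; see [default_library()].
#' @param tol convergence tolerance on fitted values; default `1e-3 * sd(Y)`.
#' @param max_iter maximum backfitting iterations (default 10).
#' @param seed integer seed driving all internal randomness.
#' @param f_vars optional character vector restricting the tree to a subset of
#'   exposure columns (used for per-component threshold discovery).
#' @param min_support minimum fraction of the sample a leaf must hold to be
#'   eligible as the designated rule (default 0.05; guards positivity).
#' @return Object of class `backfit_model`: the selected tree (`f_fit`), the
#'   covariate ensemble (`h_fit`), fitted components, `risk_trace`,
#'   `n_iterations`, `converged`, `no_rule` (TRUE when the root-only model
#'   won), `best_tree_cv_risk` and bookkeeping needed by [extract_rules()].
#' @export
iterative_backfit <- function(data, grid = tree_grid(), w_library = default_library(),
                              tol = NULL, max_iter = 10L, seed = 1L,
                              f_vars = NULL, min_support = 0.05) {
  n <- n_obs(data)
  if (n < 30L) {
    stop(sprintf("sample too small for backfitting: n = %d < 30", n))
  }
  y <- data$outcome
  f_vars <- f_vars %||% colnames(data$exposures)
  A <- data$exposures[, f_vars, drop = FALSE]
  W <- data$covariates
  if (is.null(tol)) tol <- 1e-3 * sd(y)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive")

  inner_folds <- assign_folds(n, 5L, seed + 17L)
  fhat <- rep(mean(y), n)
  hhat <- rep(0, n)
  h_fit <- NULL
  f_sel <- list(tree = NULL, grid_row = 1L, cv_risk = var(y) * (n - 1) / n,
                no_split = TRUE)
  mse <- mean((y - fhat - hhat)^2)
  risk_trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    n_iter <- it
    prev_fit <- fhat + hhat

    if (ncol(W) > 0L) {
      h_cand <- fit_ensemble(W, y - fhat, library = w_library, inner_V = 5L,
                             loss = "se", seed = seed + 1000L)
      hhat_cand <- predict(h_cand, W)
      if (mean((y - fhat - hhat_cand)^2) <= mse + 1e-9) {
        h_fit <- h_cand
        hhat <- hhat_cand
        mse <- mean((y - fhat - hhat)^2)
      }
    }

    rf <- y - hhat
    f_cand <- select_tree(A, rf, grid, inner_folds)
    fhat_cand <- if (f_cand$no_split) rep(mean(rf), n) else cpp_tree_predict(f_cand$tree, A)
    if (mean((y - fhat_cand - hhat)^2) <= mse + 1e-9) {
      f_sel <- f_cand
      fhat <- fhat_cand
      mse <- mean((y - fhat - hhat)^2)
    }

    risk_trace <- c(risk_trace, mse)
    if (max(abs(fhat + hhat - prev_fit)) < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      f_fit = f_sel, h_fit = h_fit, f_vars = f_vars,
      fhat = fhat, hhat = hhat, partial_residual = y - hhat,
      n_iterations = n_iter, risk_trace = risk_trace, converged = converged,
      no_rule = f_sel$no_split, best_tree_cv_risk = f_sel$cv_risk,
      tree_grid = grid, min_support = min_support, n = n, seed = seed
    ),
    class = "backfit_model"
  )
}

#' @export
print.backfit_model <- function(x, ...) {
  cat(sprintf("<backfit_model> n = %d, iterations = %d, converged = %s\n",
              x$n, x$n_iterations, x$converged))
  if (x$no_rule) {
    cat("  root-only tree selected: no exposure rule found\n")
  } else {
    g <- x$tree_grid[x$f_fit$grid_row, ]
    cat(sprintf("  best tree: depth %d, min leaf frac %.2f, cv risk %.5g\n",
                g$max_depth, g$min_leaf_frac, x$best_tree_cv_risk))
  }
  invisible(x)
}

# Depth-first collection of root-to-leaf interval bounds from a fitted tree.
tree_leaf_paths <- function(tree, var_names) {
  p <- length(var_names)
  leaves <- list()
  walk <- function(k, lower, upper) {
    f <- tree$feature[k + 1L]
    if (f < 0L) {
      leaves[[length(leaves) + 1L]] <<- list(node = k + 1L, lower = lower,
                                             upper = upper, n = tree$n[k + 1L],
                                             pred = tree$pred[k + 1L])
      return(invisible(NULL))
    }
    thr <- tree$threshold[k + 1L]
    lo_l <- lower; up_l <- upper
    up_l[f + 1L] <- min(up_l[f + 1L], thr)
    walk(tree$left[k + 1L], lo_l, up_l)
    lo_r <- lower
    lo_r[f + 1L] <- max(lo_r[f + 1L], thr)
    walk(tree$right[k + 1L], lo_r, upper)
  }
  walk(0L, rep(-Inf, p), rep(Inf, p))
  leaves
}

#' Extract leaf rules from a fitted backfit model
#'
#' One [mixture_rule()] per leaf of the selected tree, each the conjunction of
#' its root-to-leaf split conditions merged per variable.  The *designated*
#' rule — the one carried into ATE estimation — is the leaf whose mean partial
#' residual departs most (in absolute value) from the overall mean partial
#' residual, among leaves holding at least `min_support * n` observations;
#' ties resolve to the smaller leaf index.  A root-only model yields an empty
#' list.
#'
#' @param model a fitted `backfit_model`.
#' @param data the [mixture_dataset()] the model was fit on (schema source for
#'   the rules).
#' @return List of [mixture_rule()]s with attributes `designated` (index into
#'   the list, or `NA` if no leaf is eligible) and `leaf_nodes`.
#' @export
extract_rules <- function(model, data) {
  if (model$no_rule) {
    out <- list()
    attr(out, "designated") <- NA_integer_
    return(out)
  }
  if (!all(model$f_vars %in% colnames(data$exposures))) {
    stop("dataset does not carry the exposure schema the model was fit on")
  }
  tree <- model$f_fit$tree
  leaves <- tree_leaf_paths(tree, model$f_vars)

  rules <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    lo <- leaves[[i]]$lower
    hi <- leaves[[i]]$upper
    constrained <- which(is.finite(lo) | is.finite(hi))
    if (!length(constrained)) constrained <- 1L      # vacuous root predicate
    rules[[i]] <- mixture_rule(model$f_vars[constrained], lo[constrained],
                               hi[constrained])
  }

  rf <- model$partial_residual
  overall <- mean(rf)
  A <- NULL  # leaf assignment comes from the stored tree on the training data
  leaf_nodes <- vapply(leaves, function(l) l$node, integer(1))
  contrast <- vapply(leaves, function(l) abs(l$pred - overall), numeric(1))
  sizes <- vapply(leaves, function(l) l$n, integer(1))
  eligible <- sizes >= model$min_support * model$n
  designated <- if (any(eligible)) {
    cand <- which(eligible)
    cand[which.max(contrast[cand])]     # which.max takes the first => smaller leaf index on ties
  } else {
    NA_integer_
  }
  attr(rules, "designated") <- designated
  attr(rules, "leaf_nodes") <- leaf_nodes
  rules
}

#' Data-adaptive thresholds for a single mixture component
#'
#' Runs the iterative backfitting with `f` restricted to single-variable trees
#' on one exposure.  The selected tree's split values become ordered
#' cutpoints; the induced half-open intervals tile the variable's range and
#' the lowest interval is the reference level for the per-component ATE
#' contrasts.
#'
#' @param data a [mixture_dataset()].
#' @param variable exposure column name.
#' @param w_library learner library for `h(W)`.
#' @param seed integer seed.
#' @param max_depths tree depths tried for the single-variable tree.
#' @param ... further arguments passed to [iterative_backfit()].
#' @return Object of class `component_thresholds`: `variable`, `cutpoints`
#'   (strictly increasing, possibly empty), `levels` (list of
#'   [mixture_rule()]s tiling the range), `reference` (the lowest level or
#'   `NULL`), `empty` flag and the underlying `model`.
#' @export
component_thresholds <- function(data, variable, w_library = default_library(),
                                 seed = 1L, max_depths = c(1L, 2L, 3L), ...) {
  if (!variable %in% colnames(data$exposures)) {
    stop(sprintf("'%s' is not an exposure column", variable))
  }
  model <- iterative_backfit(
    data,
    grid = tree_grid(max_depths = max_depths, min_leaf_fracs = c(0.05, 0.1)),
    w_library = w_library, seed = seed, f_vars = variable, ...
  )
  cutpoints <- if (model$no_rule) {
    numeric(0)
  } else {
    tr <- model$f_fit$tree
    sort(unique(tr$threshold[tr$feature >= 0]))
  }
  levels <- list()
  reference <- NULL
  if (length(cutpoints)) {
    bounds <- c(-Inf, cutpoints, Inf)
    for (j in seq_len(length(bounds) - 1L)) {
      levels[[j]] <- mixture_rule(variable, bounds[j], bounds[j + 1L],
                                  provenance = sprintf("%s level %d", variable, j))
    }
    reference <- levels[[1L]]
  }
  structure(
    list(variable = variable, cutpoints = cutpoints, levels = levels,
         reference = reference, empty = !length(cutpoints), model = model),
    class = "component_thresholds"
  )
}

#' @export
print.component_thresholds <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<component_thresholds> %s: no data-adaptive cutpoints found\n",
                x$variable))
  } else {
    cat(sprintf("<component_thresholds> %s: cutpoints %s (%d levels)\n",
                x$variable, paste(signif(x$cutpoints, 5), collapse = ", "),
                length(x$levels)))
  }
  invisible(x)
}
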