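#' Candidate learner specification
#'
#' A learner is identified by a family name plus hyperparameters.  Available
#' families: `"mean"` (grand mean), `"linear"` (OLS, or logistic regression
#' under the log-likelihood loss), `"tree"` (axis-aligned regression tree,
#' hyperparameters `max_depth`, `min_leaf_frac`), `"bagged_trees"`
#' (bootstrap-aggregated trees, hyperparameters `n_trees`, `max_depth`,
#' `min_leaf_frac`) and `"knn_mean"` (mean outcome of the `k` nearest
#' neighbours in standardized Euclidean distance).
#'
#' @param name unique identifier within a library.
#' @param family one of `"mean"`, `"linear"`, `"tree"`, `"bagged_trees"`,
#'   `"knn_mean"`.
#' @param ... hyperparameters (name = value).
#' @return Object of class `learner_spec`.
#' @export
learner_spec <- function(name, family, ...) {
  family <- match.arg(family, c("mean", "linear", "tree", "bagged_trees", "knn_mean"))
  structure(list(name = name, family = family, hyper = list(...)),
            class = "learner_spec")
}

#' Default learner library
#'
#' Mean-only, linear, a depth-4 tree and 25 bagged depth-4 trees: together
#' they cover constant, linear and nonlinear regimes at desk scale.
#'
#' @return List of [learner_spec()]s.
#' @export
default_library <- function() {
  list(
    learner_spec("mean", "mean"),
    learner_spec("linear", "linear"),
    learner_spec("tree_d4", "tree", max_depth = 4, min_leaf_frac = 0.02),
    learner_spec("bagged_d4", "bagged_trees", n_trees = 25, max_depth = 4,
                 min_leaf_frac = 0.02)
  )
}

# A fast small library for settings where the truth is low-dimensional and
# compute matters (heavy simulation loops).
fast_library <- function() {
  list(
    learner_spec("mean", "mean"),
    learner_spec("linear", "linear"),
    learner_spec("tree_d3", "tree", max_depth = 3, min_leaf_frac = 0.05)
  )
}

min_leaf_from_frac <- function(frac, n) max(1L, as.integer(ceiling(frac * n)))

# Fit a single learner.  Returns an opaque handle with family + state;
# predictions go through predict_learner().  `binary` switches the linear
# learner to logistic regression.
fit_learner <- function(spec, X, y, binary = FALSE, seed = 0L) {
  n <- length(y)
  obj <- switch(spec$family,
    mean = list(mu = mean(y)),
    linear = {
      if (ncol(X) == 0L) {
        list(mu = mean(y), empty = TRUE)
      } else if (binary) {
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, X), y, family = stats::binomial())
        )
        co <- fit$coefficients
        co[!is.finite(co)] <- 0
        list(coef = co, logistic = TRUE)
      } else {
        qx <- qr(cbind(1, X))
        co <- qr.coef(qx, y)
        co[!is.finite(co)] <- 0
        list(coef = co, logistic = FALSE)
      }
    },
    tree = {
      ml <- min_leaf_from_frac(spec$hyper$min_leaf_frac %||% 0.05, n)
      if (ncol(X) == 0L) {
        list(mu = mean(y), empty = TRUE)
      } else {
        list(tree = cpp_tree_fit(X, y, spec$hyper$max_depth %||% 4L, ml))
      }
    },
    bagged_trees = {
      ml <- min_leaf_from_frac(spec$hyper$min_leaf_frac %||% 0.02, n)
      B <- spec$hyper$n_trees %||% 25L
      if (ncol(X) == 0L) {
        list(mu = mean(y), empty = TRUE)
      } else {
        boot <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), n, B))
        list(trees = cpp_bag_fit(X, y, boot, spec$hyper$max_depth %||% 4L, ml))
      }
    },
    knn_mean = {
      k <- spec$hyper$k %||% 10L
      sds <- if (ncol(X)) apply(X, 2, sd) else numeric(0)
      sds[!is.finite(sds) | sds == 0] <- 1
      list(X = sweep(X, 2, sds, "/"), y = y, k = min(k, n), sds = sds,
           empty = ncol(X) == 0L, mu = mean(y))
    }
  )
  obj$family <- spec$family
  obj
}

predict_learner <- function(obj, X) {
  n <- nrow(X)
  if (isTRUE(obj$empty)) return(rep(obj$mu, n))
  switch(obj$family,
    mean = rep(obj$mu, n),
    linear = {
      eta <- drop(cbind(1, X) %*% obj$coef)
      if (isTRUE(obj$logistic)) expit(eta) else eta
    },
    tree = cpp_tree_predict(obj$tree, X),
    bagged_trees = cpp_bag_predict(obj$trees, X),
    knn_mean = {
      Xs <- sweep(X, 2, obj$sds, "/")
      out <- numeric(n)
      for (i in seq_len(n)) {
        d2 <- colSums((t(obj$X) - Xs[i, ])^2)
        out[i] <- mean(obj$y[order(d2)[seq_len(obj$k)]])
      }
      out
    }
  )
}
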