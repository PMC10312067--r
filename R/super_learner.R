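#' Cross-validated convex ensemble ("super learner")
#'
#' Fits every learner in the library on inner-CV training folds, collects
#' held-out predictions, and finds the convex weight vector minimizing the
#' held-out loss of the weighted combination.  For squared-error loss the
#' simplex-constrained least-squares problem is solved exactly by active-set
#' enumeration over the (small) library; for binary negative log-likelihood a
#' Frank-Wolfe line search starts at the best single learner, so in both cases
#' the ensemble's held-out risk never exceeds that of the best single learner.
#' Learners that error are assigned weight zero and infinite risk.
#'
#' @param X numeric feature matrix (n x d; d may be 0).
#' @param y response vector; for `loss = "nll"` coded 0/1 (probabilities are
#'   also tolerated for the fluctuation use-case).
#' @param library list of [learner_spec()]s with unique names.
#' @param inner_V number of inner CV folds (default 5).
#' @param loss `"se"` (squared error) or `"nll"` (binomial negative
#'   log-likelihood, predictions clipped to `[0.001, 0.999]`).
#' @param seed integer seed; all randomness (fold split, bootstrap draws)
#'   derives from it, so a fixed seed gives bitwise-identical weights.
#' @return Object of class `ensemble_fit`: learners, `weights` on the
#'   probability simplex, per-learner `cv_risks`, the ensemble's own
#'   `cv_risk`, `inner_V`, `loss`, fitted base models and the names of any
#'   `failed` learners.
#' @export
fit_ensemble <- function(X, y, library = default_library(), inner_V = 5L,
                         loss = c("se", "nll"), seed = 1L) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("rows(X) must equal length(y)")
  if (n < 2L * inner_V) stop("need at least 2 * inner_V observations")
  if (!length(library)) stop("learner library must be non-empty")
  nms <- vapply(library, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("learner names must be unique within a library")
  binary <- loss == "nll"

  folds <- assign_folds(n, inner_V, seed)
  L <- length(library)
  Z <- matrix(NA_real_, n, L, dimnames = list(NULL, nms))
  failed <- rep(FALSE, L)
  for (l in seq_len(L)) {
    ok <- TRUE
    for (v in seq_len(inner_V)) {
      tr <- fold_param_idx(folds, v)
      te <- fold_est_idx(folds, v)
      p <- tryCatch({
        fit <- fit_learner(library[[l]], X[tr, , drop = FALSE], y[tr],
                           binary = binary, seed = seed + 7L * v + 101L * l)
        predict_learner(fit, X[te, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(p) || !all(is.finite(p))) { ok <- FALSE; break }
      Z[te, l] <- p
    }
    failed[l] <- !ok
  }
  if (all(failed)) stop("ensemble fit failed: every learner errored")
  if (binary) Z <- clip(Z, .PROB_EPS, 1 - .PROB_EPS)

  risk_fun <- if (loss == "se") {
    function(p) mean((y - p)^2)
  } else {
    function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  cv_risks <- rep(Inf, L)
  names(cv_risks) <- nms
  live <- which(!failed)
  for (l in live) cv_risks[l] <- risk_fun(Z[, l])

  w <- rep(0, L)
  if (length(live) == 1L) {
    w[live] <- 1
  } else {
    Zl <- Z[, live, drop = FALSE]
    wl <- if (loss == "se") {
      simplex_ls(Zl, y)
    } else {
      simplex_nll(Zl, y, start = which.min(cv_risks[live]))
    }
    w[live] <- wl
  }
  ens_pred <- drop(Z[, w > 0, drop = FALSE] %*% w[w > 0])
  if (binary) ens_pred <- clip(ens_pred, .PROB_EPS, 1 - .PROB_EPS)
  cv_risk <- risk_fun(ens_pred)

  full_fits <- vector("list", L)
  for (l in which(w > 0)) {
    full_fits[[l]] <- fit_learner(library[[l]], X, y, binary = binary,
                                  seed = seed + 13L * l)
  }

  structure(
    list(
      learners = library, weights = w, cv_risks = cv_risks, cv_risk = cv_risk,
      inner_V = as.integer(inner_V), loss = loss, fits = full_fits,
      failed = nms[failed], d = ncol(X), seed = as.integer(seed)
    ),
    class = "ensemble_fit"
  )
}

#' Predict from a fitted ensemble
#'
#' Weighted sum of the base learners' full-data fits.  Under the binary loss
#' the output is clipped to `[0.001, 0.999]` so downstream logits stay finite.
#'
#' @param object an `ensemble_fit`.
#' @param newdata numeric feature matrix with the training schema (same
#'   number of columns).
#' @param ... unused.
#' @return Numeric prediction vector.
#' @export
predict.ensemble_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) {
    stop(sprintf("schema mismatch: ensemble was trained on %d feature(s), got %d",
                 object$d, ncol(newdata)))
  }
  out <- rep(0, nrow(newdata))
  for (l in which(object$weights > 0)) {
    out <- out + object$weights[l] * predict_learner(object$fits[[l]], newdata)
  }
  if (object$loss == "nll") out <- clip(out, .PROB_EPS, 1 - .PROB_EPS)
  out
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> loss = %s, inner_V = %d\n", x$loss, x$inner_V))
  nms <- vapply(x$learners, function(s) s$name, character(1))
  for (l in seq_along(nms)) {
    cat(sprintf("  %-12s weight = %.4f  cv_risk = %.6g\n", nms[l],
                x$weights[l], x$cv_risks[l]))
  }
  invisible(x)
}

# Exact simplex-constrained least squares:  min ||y - Z w||^2  s.t. w >= 0,
# sum w = 1.  With L <= ~6 columns, enumerate every non-empty support set,
# solve the equality-constrained problem on that face via its KKT system, and
# keep the feasible solution with lowest risk.  Deterministic; vertices are in
# the candidate set, so the solution never does worse than the best single
# learner.
simplex_ls <- function(Z, y) {
  L <- ncol(Z)
  G <- crossprod(Z)
  b <- crossprod(Z, y)
  best_w <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^L - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(L) - 1L)) != 0L)
    k <- length(S)
    KKT <- rbind(cbind(2 * G[S, S, drop = FALSE], rep(1, k)), c(rep(1, k), 0))
    sol <- tryCatch(solve(KKT, c(2 * b[S], 1)), error = function(e) NULL)
    if (is.null(sol)) next
    wS <- sol[seq_len(k)]
    if (any(wS < -1e-9)) next
    wS <- pmax(wS, 0)
    wS <- wS / sum(wS)
    w <- rep(0, L)
    w[S] <- wS
    obj <- sum((y - drop(Z %*% w))^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_w <- w
    }
  }
  if (is.null(best_w)) {                  # fall back to best vertex
    risks <- colSums((y - Z)^2)
    best_w <- rep(0, L)
    best_w[which.min(risks)] <- 1
  }
  best_w
}

# Convex minimisation of binomial NLL over the simplex by Frank-Wolfe with an
# exact (1-D golden-section) line search, started at the best single learner.
# Each step is monotone, so the final risk is <= the best vertex risk.
simplex_nll <- function(Z, y, start, max_iter = 60L) {
  Z <- clip(Z, .PROB_EPS, 1 - .PROB_EPS)
  L <- ncol(Z)
  nll <- function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  w <- rep(0, L)
  w[start] <- 1
  p <- drop(Z %*% w)
  obj <- nll(p)
  for (it in seq_len(max_iter)) {
    grad_p <- (-(y / p) + (1 - y) / (1 - p)) / length(y)
    grad_w <- drop(crossprod(Z, grad_p))
    s <- which.min(grad_w)
    dirn <- drop(Z[, s]) - p
    f_gamma <- function(g) nll(clip(p + g * dirn, .PROB_EPS, 1 - .PROB_EPS))
    opt <- optimize(f_gamma, c(0, 1), tol = 1e-10)
    if (opt$objective < obj - 1e-12) {
      g <- opt$minimum
      w <- (1 - g) * w
      w[s] <- w[s] + g
      p <- p + g * dirn
      obj <- opt$objective
    } else {
      break
    }
  }
  w / sum(w)
}
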