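#' Mixture dataset container
#'
#' Bundles the three blocks every estimator in the package works on: a matrix
#' `A` of continuous exposures (the "mixture"), a matrix `W` of covariates and
#' an outcome vector `Y`.  Categorical covariates are dummy (one-hot, first
#' level dropped) encoded at construction and the encoding is recorded so new
#' data can be mapped onto the same schema.  Rows with missing values in any
#' block are dropped with a recorded count (complete-case analysis).
#'
#' @param exposures data.frame or matrix of continuous exposures, n x p,
#'   with column names.  Every column must be numeric with at least two
#'   distinct values.
#' @param covariates data.frame or matrix of covariates, n x q (q may be 0).
#'   Numeric columns are passed through; factor/character columns are dummy
#'   encoded.
#' @param outcome numeric vector of length n; binary outcomes must be coded
#'   0/1.
#' @param ids optional vector of unique observation identifiers; defaults to
#'   `seq_len(n)`.
#'
#' @return An object of class `mixture_dataset`: a list with elements
#'   `exposures` (numeric matrix), `covariates` (numeric matrix, possibly
#'   0-column), `outcome`, `ids`, `outcome_type` (`"continuous"` or
#'   `"binary"`), `n_dropped` (rows removed for missingness) and `encoding`
#'   (dummy-encoding map for categorical covariates).
#' @export
mixture_dataset <- function(exposures, covariates = NULL, outcome, ids = NULL) {
  exposures <- as.data.frame(exposures)
  if (ncol(exposures) < 1L) stop("at least one exposure column is required")
  if (is.null(colnames(exposures))) stop("exposure columns must be named")
  n0 <- nrow(exposures)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(n0))
  }
  covariates <- as.data.frame(covariates)
  outcome <- as.vector(outcome)
  if (nrow(covariates) != n0 || length(outcome) != n0) {
    stop("exposures, covariates and outcome must have the same number of rows")
  }
  if (is.null(ids)) ids <- seq_len(n0)
  if (anyDuplicated(ids)) stop("`ids` must be unique")

  ok <- stats::complete.cases(exposures) &
    (ncol(covariates) == 0L | stats::complete.cases(covariates)) &
    !is.na(outcome)
  n_dropped <- sum(!ok)
  exposures <- exposures[ok, , drop = FALSE]
  covariates <- covariates[ok, , drop = FALSE]
  outcome <- outcome[ok]
  ids <- ids[ok]
  n <- length(outcome)
  if (n < 1L) stop("no complete rows remain after dropping missing values")

  for (nm in colnames(exposures)) {
    if (!is.numeric(exposures[[nm]])) {
      stop(sprintf("exposure column '%s' is not numeric", nm))
    }
    if (length(unique(exposures[[nm]])) < 2L) {
      stop(sprintf("exposure column '%s' has fewer than 2 distinct values", nm))
    }
  }
  A <- as.matrix(exposures)
  storage.mode(A) <- "double"

  enc <- list()
  wcols <- list()
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      wcols[[nm]] <- as.double(v)
    } else {
      v <- as.factor(v)
      lev <- levels(v)
      enc[[nm]] <- lev
      for (l in lev[-1L]) {           # drop first level: treatment coding
        wcols[[paste0(nm, "_", l)]] <- as.double(v == l)
      }
    }
  }
  W <- if (length(wcols)) {
    do.call(cbind, wcols)
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  rownames(W) <- NULL

  if (!is.numeric(outcome)) stop("outcome must be numeric (binary coded 0/1)")
  outcome_type <- if (all(outcome %in% c(0, 1))) "binary" else "continuous"

  structure(
    list(
      exposures = A, covariates = W, outcome = as.double(outcome), ids = ids,
      outcome_type = outcome_type, n_dropped = n_dropped, encoding = enc
    ),
    class = "mixture_dataset"
  )
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf(
    "<mixture_dataset> n = %d, exposures = %d (%s), covariates = %d, outcome = %s\n",
    length(x$outcome), ncol(x$exposures),
    paste(colnames(x$exposures), collapse = ", "),
    ncol(x$covariates), x$outcome_type
  ))
  if (x$n_dropped > 0) cat(sprintf("  %d rows dropped for missingness\n", x$n_dropped))
  invisible(x)
}

n_obs <- function(data) length(data$outcome)

# Row subset preserving the schema.
subset_dataset <- function(data, idx) {
  structure(
    list(
      exposures = data$exposures[idx, , drop = FALSE],
      covariates = data$covariates[idx, , drop = FALSE],
      outcome = data$outcome[idx],
      ids = data$ids[idx],
      outcome_type = data$outcome_type,
      n_dropped = 0L,
      encoding = data$encoding
    ),
    class = "mixture_dataset"
  )
}

#' Load a mixture dataset from CSV
#'
#' Reads a headered CSV and assembles a [mixture_dataset()] from named columns.
#' Rows with missing values are dropped; the count is stored in the result and
#' reported via `message()`.
#'
#' @param path path to a CSV file with a header row.
#' @param exposure_cols character vector of exposure column names.
#' @param covariate_cols character vector of covariate column names (may be
#'   empty).
#' @param outcome_col single outcome column name.
#' @return A [mixture_dataset()].
#' @export
load_mixture_csv <- function(path, exposure_cols, covariate_cols, outcome_col) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c(exposure_cols, covariate_cols, outcome_col), colnames(df))
  if (length(missing)) {
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing, collapse = ", ")))
  }
  d <- mixture_dataset(
    exposures = df[, exposure_cols, drop = FALSE],
    covariates = df[, covariate_cols, drop = FALSE],
    outcome = df[[outcome_col]]
  )
  if (d$n_dropped > 0) {
    message(sprintf("dropped %d incomplete rows while loading %s", d$n_dropped, path))
  }
  d
}

#' V-fold assignment into estimation / parameter-generating samples
#'
#' Produces a balanced random partition of `n` observations into `V` folds
#' (fold sizes differ by at most one).  For fold `v` the estimation sample is
#' the set of observations labelled `v` and the parameter-generating sample is
#' its complement.  The assignment is a deterministic function of
#' `(n, V, seed)`.
#'
#' @param n number of observations.
#' @param V number of folds, `2 <= V <= n`.
#' @param seed integer seed.
#' @return Object of class `fold_assignment`: list with `V`, `labels`
#'   (length-n integer vector in `1..V`) and `seed`.
#' @export
assign_folds <- function(n, V, seed) {
  n <- as.integer(n); V <- as.integer(V)
  if (is.na(V) || V < 2L || V > n) {
    stop(sprintf("invalid fold count: V must satisfy 2 <= V <= n (got V=%s, n=%s)", V, n))
  }
  labels <- with_seed(seed, {
    base <- rep(seq_len(V), length.out = n)
    sample(base, n, replace = FALSE)
  })
  structure(list(V = V, labels = as.integer(labels), seed = as.integer(seed)),
            class = "fold_assignment")
}

# Index helpers: estimation sample = fold v, parameter-generating = complement.
fold_est_idx <- function(folds, v) which(folds$labels == v)
fold_param_idx <- function(folds, v) which(folds$labels != v)
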