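#' Mixture rules: conjunctions of interval predicates
#'
#' A mixture rule is a conjunction of half-open interval predicates
#' `lower < a <= upper` on named exposure variables, the canonical form a
#' decision-tree leaf takes.  Multiple predicates on the same variable are
#' merged (interval intersection) at construction.  The half-open convention
#' means contiguous tree splits tile the real line without overlap: a split at
#' `c` produces `(-Inf, c]` and `(c, +Inf)`.
#'
#' @param vars character vector of exposure variable names (one per predicate;
#'   repeats are merged).
#' @param lowers numeric vector of lower bounds (`-Inf` allowed).
#' @param uppers numeric vector of upper bounds (`+Inf` allowed).
#' @param provenance free-text origin tag, e.g. `"fold 3"` or `"pooled/union"`.
#' @return Object of class `mixture_rule` with a `predicates` data.frame
#'   (`var`, `lower`, `upper`), a canonical `description` string and
#'   `provenance`.
#' @export
mixture_rule <- function(vars, lowers = -Inf, uppers = Inf, provenance = NA_character_) {
  if (length(vars) < 1L) stop("a rule needs at least one predicate")
  k <- length(vars)
  lowers <- rep_len(as.double(lowers), k)
  uppers <- rep_len(as.double(uppers), k)
  uv <- unique(vars)
  lo <- vapply(uv, function(v) max(lowers[vars == v]), 0.0)
  hi <- vapply(uv, function(v) min(uppers[vars == v]), 0.0)
  bad <- !(lo < hi)
  if (any(bad)) {
    stop(sprintf("empty interval for variable(s): %s",
                 paste(uv[bad], collapse = ", ")))
  }
  r <- structure(
    list(
      predicates = data.frame(var = uv, lower = unname(lo), upper = unname(hi),
                              stringsAsFactors = FALSE),
      provenance = provenance
    ),
    class = "mixture_rule"
  )
  r$description <- serialize_rule(r)
  r
}

#' Serialize a rule to its canonical text form
#'
#' Emits `var > lower & var <= upper` clauses (infinite bounds printed as
#' `-Inf`/`Inf` only when the predicate is otherwise vacuous), predicates
#' ordered by variable name.  `parse_rule(serialize_rule(r))` is the identity.
#'
#' @param rule a [mixture_rule()].
#' @return Single string.
#' @export
serialize_rule <- function(rule) {
  p <- rule$predicates[order(rule$predicates$var), , drop = FALSE]
  clauses <- character(0)
  for (i in seq_len(nrow(p))) {
    cl <- character(0)
    if (is.finite(p$lower[i])) cl <- c(cl, sprintf("%s > %.15g", p$var[i], p$lower[i]))
    if (is.finite(p$upper[i])) cl <- c(cl, sprintf("%s <= %.15g", p$var[i], p$upper[i]))
    if (!length(cl)) cl <- sprintf("%s > -Inf", p$var[i])   # vacuous predicate
    clauses <- c(clauses, cl)
  }
  paste(clauses, collapse = " & ")
}

#' Parse a rule string
#'
#' Grammar: `var OP number (& var OP number)*` with `OP` one of
#' `>`, `>=`, `<`, `<=` and `number` a decimal literal or `Inf`/`-Inf`.
#' Because the package's interval convention is half-open `(lower, upper]`,
#' `>=` is coerced to `>` and `<` to `<=`; tree thresholds are midpoints
#' between observed values so no data point lies on a boundary.
#'
#' @param text rule string.
#' @param provenance origin tag stored on the parsed rule.
#' @return A [mixture_rule()].
#' @export
parse_rule <- function(text, provenance = NA_character_) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("rule text must be a single non-empty string")
  }
  clauses <- strsplit(text, "&", fixed = TRUE)[[1]]
  pat <- "^\\s*([A-Za-z_.][A-Za-z0-9_.]*)\\s*(>=|<=|>|<)\\s*([-+]?(Inf|[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?))\\s*$"
  vars <- character(0); lowers <- numeric(0); uppers <- numeric(0)
  for (i in seq_along(clauses)) {
    m <- regmatches(clauses[i], regexec(pat, clauses[i]))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse rule clause %d: '%s'", i, trimws(clauses[i])))
    }
    v <- m[2]; op <- m[3]; num <- as.numeric(m[4])
    vars <- c(vars, v)
    if (op %in% c(">", ">=")) {
      lowers <- c(lowers, num); uppers <- c(uppers, Inf)
    } else {
      lowers <- c(lowers, -Inf); uppers <- c(uppers, num)
    }
  }
  mixture_rule(vars, lowers, uppers, provenance = provenance)
}

#' @export
print.mixture_rule <- function(x, ...) {
  cat("<mixture_rule>", x$description)
  if (!is.na(x$provenance)) cat(sprintf("  [%s]", x$provenance))
  cat("\n")
  invisible(x)
}

#' @export
format.mixture_rule <- function(x, ...) x$description

#' Evaluate a rule on a dataset
#'
#' Returns the 0/1 membership indicator: entry `i` is 1 iff observation `i`
#' satisfies every predicate under the half-open convention
#' `lower < a <= upper`.
#'
#' @param rule a [mixture_rule()].
#' @param data a [mixture_dataset()] whose exposures contain every variable
#'   named in the rule.
#' @return Integer vector of 0/1 of length `n`.
#' @export
evaluate_rule <- function(rule, data) {
  A <- data$exposures
  unknown <- setdiff(rule$predicates$var, colnames(A))
  if (length(unknown)) {
    stop(sprintf("rule names variable(s) not in the exposure schema: %s",
                 paste(unknown, collapse = ", ")))
  }
  ind <- rep(TRUE, nrow(A))
  for (i in seq_len(nrow(rule$predicates))) {
    a <- A[, rule$predicates$var[i]]
    ind <- ind & (a > rule$predicates$lower[i]) & (a <= rule$predicates$upper[i])
  }
  as.integer(ind)
}

#' Union of rules: the pooled estimand's treatment indicator
#'
#' Fold-specific rules generally differ; the pooled estimand contrasts
#' membership in the union of the fold rules against its complement.
#'
#' @param rules non-empty list of [mixture_rule()]s.
#' @param data a [mixture_dataset()].
#' @return List with `indicator` (0/1 vector: 1 iff any rule covers the row)
#'   and `description` (the disjunction, member rules parenthesised and
#'   joined by `" | "`; duplicates removed).
#' @export
rule_union <- function(rules, data) {
  if (!length(rules)) stop("rule_union needs at least one rule")
  inds <- vapply(rules, evaluate_rule, integer(n_obs(data)), data = data)
  inds <- matrix(inds, nrow = n_obs(data))
  descs <- unique(vapply(rules, function(r) r$description, character(1)))
  list(
    indicator = as.integer(rowSums(inds) > 0),
    description = paste(sprintf("(%s)", descs), collapse = " | ")
  )
}
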