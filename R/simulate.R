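#' Simulation configuration for mixture datasets
#'
#' Describes a structural model with a known rectangular effect region in
#' exposure space.  Covariates are independent standard normals; exposure `j`
#' is `alpha * (c_j' W) + Uniform(0, 2)` with unit-norm loading vectors `c_j`
#' and `alpha = confounding_strength`; a continuous outcome is
#' `tau * 1\{A in true_region\} + beta' W + N(0, noise_sd^2)` with
#' `beta = confounding_strength * b`; a binary outcome is Bernoulli with the
#' same linear predictor passed through the logistic link.  Loadings `c_j` and
#' `b` are deterministic functions of the seed, so the ground truth is fully
#' reproducible.  Because the indicator enters the continuous outcome
#' additively, the true ATE of the true region is exactly `tau` at any
#' confounding strength, while the unadjusted difference in means is biased
#' whenever `confounding_strength > 0`.
#'
#' @param n sample size.
#' @param p number of exposures.
#' @param q number of covariates.
#' @param true_region a [mixture_rule()] on exposures `a1..ap` (names
#'   `a1`, `a2`, ...).
#' @param effect_size tau, the causal effect of region membership.
#' @param confounding_strength covariate loading on both exposures and
#'   outcome (0 = no confounding).
#' @param noise_sd residual standard deviation (continuous outcome).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param seed integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n, p = 3L, q = 2L,
                       true_region = mixture_rule(c("a1", "a2"), c(0.5, 0.5), c(Inf, Inf)),
                       effect_size = 5, confounding_strength = 0,
                       noise_sd = 0.2, outcome_type = c("continuous", "binary"),
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  if (n < 1L) stop("n must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(true_region)) {
    bad <- !true_region$predicates$var %in% paste0("a", seq_len(p))
    if (any(bad)) stop("true_region names exposures outside a1..ap")
  }
  structure(
    list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
         true_region = true_region, effect_size = effect_size,
         confounding_strength = confounding_strength, noise_sd = noise_sd,
         outcome_type = outcome_type, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Named simulation presets
#'
#' * `"null"`: no exposure effect (`tau = 0`), mild covariate-only signal.
#' * `"main-effect-1d"`: step effect of size 3 at `a1 > 1`, no confounding.
#' * `"interaction-2d"`: effect 5 in the region `a1 > 0.5 & a2 > 0.5`,
#'   noise sd 0.2, no confounding.
#' * `"confounded-interaction"`: same region/effect with confounding
#'   strength 1 (the unadjusted difference in means is biased by several
#'   times its sampling error at the design n of 500).
#' * `"binary-outcome"`: binary Y, logistic effect 1.5 of the 2-d region,
#'   confounding strength 0.3.
#'
#' @param preset preset name.
#' @param n sample size.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
preset_config <- function(preset, n = 500L, seed = 1L) {
  presets <- c("null", "main-effect-1d", "interaction-2d",
               "confounded-interaction", "binary-outcome")
  if (!preset %in% presets) {
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(presets, collapse = ", ")))
  }
  region2d <- mixture_rule(c("a1", "a2"), c(0.5, 0.5), c(Inf, Inf))
  switch(preset,
    "null" = sim_config(n, p = 3L, q = 2L, true_region = region2d,
                        effect_size = 0, confounding_strength = 0.3,
                        noise_sd = 1, seed = seed),
    "main-effect-1d" = sim_config(n, p = 3L, q = 2L,
                                  true_region = mixture_rule("a1", 1, Inf),
                                  effect_size = 3, confounding_strength = 0,
                                  noise_sd = 0.2, seed = seed),
    "interaction-2d" = sim_config(n, p = 3L, q = 2L, true_region = region2d,
                                  effect_size = 5, confounding_strength = 0,
                                  noise_sd = 0.2, seed = seed),
    "confounded-interaction" = sim_config(n, p = 3L, q = 2L,
                                          true_region = region2d,
                                          effect_size = 5,
                                          confounding_strength = 1,
                                          noise_sd = 0.2, seed = seed),
    "binary-outcome" = sim_config(n, p = 3L, q = 2L, true_region = region2d,
                                  effect_size = 1.5, confounding_strength = 0.3,
                                  noise_sd = 0, outcome_type = "binary",
                                  seed = seed)
  )
}

# Structural coefficients derived deterministically from the seed (but not
# from n), so ground truth is stable across sample sizes.
sim_structure <- function(config) {
  with_seed(config$seed + 990001L, {
    C <- matrix(rnorm(config$p * config$q), config$p, config$q)
    if (config$q > 0L) C <- C / pmax(sqrt(rowSums(C^2)), 1e-12)
    b <- if (config$q > 0L) rnorm(config$q) else numeric(0)
    list(C = C, beta = config$confounding_strength * b)
  })
}

#' Simulate a mixture dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @param data_seed optional separate seed for the data draw; defaults to
#'   `config$seed`.  Varying `data_seed` while keeping `config$seed` fixed
#'   yields replicate datasets from one structural world (same loadings,
#'   same ground truth).
#' @return List with `data` (a [mixture_dataset()]) and `truth` (structural
#'   parameters: loadings `C`, outcome coefficients `beta`, `tau`,
#'   `true_region`, region membership indicator and, for a continuous
#'   outcome, the exact true ATE `tau`).
#' @export
simulate_mixtures <- function(config, data_seed = NULL) {
  st <- sim_structure(config)
  out <- with_seed(data_seed %||% config$seed, {
    n <- config$n; p <- config$p; q <- config$q
    W <- matrix(rnorm(n * q), n, q)
    shift <- if (q > 0L) {
      config$confounding_strength * (W %*% t(st$C))
    } else {
      matrix(0, n, p)
    }
    A <- shift + matrix(runif(n * p, 0, 1.5), n, p)
    colnames(A) <- paste0("a", seq_len(p))
    colnames(W) <- if (q > 0L) paste0("w", seq_len(q)) else character(0)

    dat0 <- mixture_dataset(as.data.frame(A),
                            if (q > 0L) as.data.frame(W) else NULL,
                            outcome = rep(0, n))
    ind <- evaluate_rule(config$true_region, dat0)
    lin <- config$effect_size * ind + if (q > 0L) drop(W %*% st$beta) else 0
    y <- if (config$outcome_type == "binary") {
      rbinom(n, 1L, expit(lin))
    } else {
      lin + rnorm(n, 0, config$noise_sd)
    }
    list(A = A, W = W, y = y, ind = ind)
  })
  data <- mixture_dataset(
    as.data.frame(out$A),
    if (config$q > 0L) as.data.frame(out$W) else NULL,
    outcome = out$y
  )
  truth <- list(
    C = st$C, beta = st$beta, tau = config$effect_size,
    true_region = config$true_region, region_indicator = out$ind,
    true_ate = if (config$outcome_type == "continuous") config$effect_size else NULL
  )
  list(data = data, truth = truth)
}

# Per-variable membership probability P(l < A_j <= u | W) for the uniform
# base draw A_j = alpha c_j'W + U(0, 1.5): overlap of (l, u] with the shifted
# support, divided by the support width.
interval_prob <- function(lo, hi, shift) {
  pmax(0, pmin(hi, shift + 1.5) - pmax(lo, shift)) / 1.5
}

# bounds for a conjunction rule as p x 2 matrix aligned to a1..ap
rule_bounds <- function(rule, p) {
  lo <- rep(-Inf, p); hi <- rep(Inf, p)
  for (i in seq_len(nrow(rule$predicates))) {
    j <- as.integer(sub("^a", "", rule$predicates$var[i]))
    lo[j] <- max(lo[j], rule$predicates$lower[i])
    hi[j] <- min(hi[j], rule$predicates$upper[i])
  }
  cbind(lo, hi)
}

# P(A in box | W) for one box given the per-variable shifts (mc_n x p).
box_prob <- function(box, shift) {
  pr <- rep(1, nrow(shift))
  for (j in seq_len(nrow(box))) {
    if (box[j, 1] >= box[j, 2]) return(rep(0, nrow(shift)))
    pr <- pr * interval_prob(box[j, 1], box[j, 2], shift[, j])
  }
  pr
}

# P(A in union of boxes | W) by inclusion-exclusion (box lists are small: one
# box per cross-validation fold).
union_prob <- function(boxes, shift) {
  k <- length(boxes)
  pr <- rep(0, nrow(shift))
  for (mask in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    inter <- boxes[[S[1]]]
    for (s in S[-1]) {
      inter <- cbind(pmax(inter[, 1], boxes[[s]][, 1]),
                     pmin(inter[, 2], boxes[[s]][, 2]))
    }
    pr <- pr + (-1)^(length(S) + 1) * box_prob(inter, shift)
  }
  pr
}

intersect_box <- function(b1, b2) {
  cbind(pmax(b1[, 1], b2[, 1]), pmin(b1[, 2], b2[, 2]))
}

#' Monte-Carlo true ATE of an arbitrary rule under the structural model
#'
#' Computes `E[Y(1{rule} = 1)] - E[Y(1{rule} = 0)]` by g-computation under the
#' structural model: for each Monte-Carlo draw of `W`, the conditional
#' probability that the exposure vector lies in the true effect region given
#' rule membership (or non-membership) is computed analytically (all sets
#' involved are axis-aligned boxes — unions of boxes are handled by
#' inclusion-exclusion — and the exposures are conditionally independent
#' shifted uniforms), and the two conditional outcome means are averaged over
#' `W`.  For the continuous additive model and `rule == true_region` this
#' returns `tau` exactly up to Monte-Carlo error.
#'
#' @param config a [sim_config()].
#' @param rule a [mixture_rule()] on the simulated exposures, or a *list* of
#'   such rules interpreted as their union (the pooled estimand).
#' @param mc_n Monte-Carlo sample size for the outer expectation over `W`
#'   (at least 1e4).
#' @param seed seed for the Monte-Carlo draw (defaults to the config seed
#'   offset so it is independent of the simulated dataset).
#' @return The ATE as a number with attribute `"se"` (Monte-Carlo standard
#'   error).
#' @export
true_ate <- function(config, rule, mc_n = 1e5, seed = NULL) {
  if (mc_n < 1e4) stop("mc_n must be at least 1e4")
  st <- sim_structure(config)
  p <- config$p; q <- config$q
  rules <- if (inherits(rule, "mixture_rule")) list(rule) else rule
  boxes <- lapply(rules, rule_bounds, p = p)
  Bt <- rule_bounds(config$true_region, p)        # the true-effect box
  seed <- seed %||% (config$seed + 777001L)

  with_seed(seed, {
    W <- matrix(rnorm(mc_n * q), mc_n, q)
    shift <- if (q > 0L) config$confounding_strength * (W %*% t(st$C)) else matrix(0, mc_n, p)
    pr_rule <- union_prob(boxes, shift)                               # P(rule | W)
    pr_true <- box_prob(Bt, shift)                                    # P(region | W)
    pr_both <- union_prob(lapply(boxes, intersect_box, b2 = Bt), shift)
    # the estimand is defined on the covariate positivity region: keep draws
    # where both rule membership and non-membership are possible (this is
    # what a propensity-truncated TMLE estimates)
    eps <- 1e-9
    keep <- pr_rule > eps & pr_rule < 1 - eps
    pr_rule <- pr_rule[keep]; pr_true <- pr_true[keep]; pr_both <- pr_both[keep]
    if (q > 0L) W <- W[keep, , drop = FALSE]
    p_region_given_1 <- pr_both / pr_rule
    p_region_given_0 <- (pr_true - pr_both) / (1 - pr_rule)
    p_region_given_1 <- clip(p_region_given_1, 0, 1)
    p_region_given_0 <- clip(p_region_given_0, 0, 1)

    bw <- if (q > 0L) drop(W %*% st$beta) else rep(0, sum(keep))
    delta <- if (config$outcome_type == "binary") {
      m1 <- p_region_given_1 * expit(config$effect_size + bw) +
        (1 - p_region_given_1) * expit(bw)
      m0 <- p_region_given_0 * expit(config$effect_size + bw) +
        (1 - p_region_given_0) * expit(bw)
      m1 - m0
    } else {
      config$effect_size * (p_region_given_1 - p_region_given_0)
    }
    out <- mean(delta)
    attr(out, "se") <- sd(delta) / sqrt(length(delta))
    out
  })
}
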