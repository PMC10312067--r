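---
title: "Tree-defined mixture exposures and cross-validated targeted learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-defined mixture exposures and cross-validated targeted learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixtree)
```

## The problem

Environmental exposures rarely come one at a time. Pollutants, metals and
pesticides are measured jointly, and the scientific question is usually about
the effect of a *region* of the joint exposure space — "what happens to the
outcome when a person's profile falls into this combination of exposure
levels?" — not about the coefficient of one pollutant in a linear model.
`mixtree` addresses this in two stages:

1. **Rule discovery.** A decision tree over the joint exposures `A` finds a
   rectangular subspace (a conjunction of interval conditions such as
   `a1 > 0.5 & a2 > 0.5`) whose membership best explains the outcome, while an
   unrestricted ensemble flexibly adjusts for covariates `W`.
2. **Estimation.** Membership in the discovered subspace is treated as a
   binary exposure and its average treatment effect (ATE),
   `E[Y(1) - Y(0)]` for membership versus the full complement, is estimated by
   targeted maximum likelihood with efficient-influence-curve (EIC) based
   inference.

Because the estimand itself is chosen by looking at the data (a *data-adaptive
parameter*), naive reuse of the same observations for discovery and inference
is overfit and anti-conservative. The package therefore uses V-fold sample
splitting throughout: in fold `v`, the observations **not** labelled `v` form
the *parameter-generating sample* (rule discovery and nuisance estimation)
and the observations labelled `v` form the *estimation sample* (targeting and
inference). Results are reported per fold and pooled.

## The semi-parametric working model

Rule discovery fits

$$E(Y \mid A, W) = f(A) + h(W)$$

by iterative backfitting, as in generalized additive models: initialize
`f` at the outcome mean and `h` at zero, then alternate between fitting `h`
to the partial residual `Y - f(A)` and `f` to `Y - h(W)` until the combined
fitted values change by less than `tol` (default `1e-3 * sd(Y)`, at most 10
iterations). Here

* `h(W)` is a cross-validated convex ensemble ("super learner") over a small
  library of learners — grand mean, linear model, a depth-4 regression tree
  and 25 bagged depth-4 trees by default — with exact simplex-constrained
  least-squares meta-learning, so the ensemble's held-out risk never exceeds
  the best single learner's;
* `f(A)` is a single regression tree selected from a hyperparameter grid
  (depths 1–3 crossed with minimum leaf fractions 0.05 and 0.1, plus the
  root-only model) by inner 5-fold cross-validated risk.

Two deliberate choices here:

* **Discrete tree selection, not a blend.** A convex blend of trees has no
  single rule set to extract; the winner-take-all selection keeps the
  parameter interpretable.
* **The one-standard-error rule.** The literal CV-risk minimiser picks a
  spurious split in roughly a fifth of pure-noise samples, because the risk
  difference between the root and a depth-1 tree is within cross-validation
  noise. We therefore select the *simplest* grid point whose CV risk is
  within one standard error of the minimum — the standard CART remedy. The
  root-only model is a first-class candidate, which is what makes "no rule
  found" an honest, reachable outcome rather than an error.
* **Monotone risk trace.** Each backfit component update is accepted only if
  it does not increase the combined in-sample risk, so the recorded
  `risk_trace` is non-increasing by construction and convergence is
  guaranteed. (Recomputing a full cross-validated risk of the combined model
  every iteration would multiply the cost of every fit for no inferential
  gain; cross-validation is used where it matters — inside the tree
  selection.)

Rules use the half-open convention `lower < a <= upper`: a split at `c`
produces `(-Inf, c]` and `(c, Inf)`, so sibling leaves tile the line without
overlap and the extracted leaf rules always partition the sample. Tree
thresholds are midpoints between adjacent observed values, so no data point
sits on a boundary.

The **designated rule** carried into estimation is the leaf whose mean
partial residual departs most, in absolute value, from the overall mean,
among leaves holding at least `min_support = 5%` of the sample (a positivity
guard); ties go to the smaller leaf index.

## Targeting and inference

For a fixed rule with indicator `d`, the nuisances are the outcome regression
`Q(d, W)` and the propensity `g(W) = P(d = 1 | W)`, both fit by the super
learner on the parameter-generating sample and predicted on the estimation
sample; `g` is truncated to `(0.025, 0.975)` by default. A continuous outcome
is mapped to `[0, 1]` using parameter-generating-sample bounds widened by 10%
(bounded-loss TMLE), which keeps the logistic fluctuation well-defined and
the updated predictions in range; the final estimate is mapped back, and the
ATE is equivariant under affine rescaling of the outcome by construction.

The targeting step fits a one-dimensional fluctuation with the clever
covariate `H(d, W) = d/g(W) - (1-d)/(1-g(W))` as a regressor against the
logit of the initial predictions; `epsilon` solves the score equation
`sum(H * (y - Q*)) = 0` by safeguarded Newton iteration (the score is
strictly monotone, so the root is unique; the test suite pins the solution
against a brute-force grid maximizer of the likelihood). After the update the
empirical mean of the EIC

$$\mathrm{EIC}_i = H(d_i, W_i)\,(Y_i - Q^*(d_i, W_i)) + Q^*(1, W_i) - Q^*(0, W_i) - \psi$$

is zero to numerical precision, the standard error is `sd(EIC)/sqrt(m)` and
95% intervals are `psi ± 1.96 se`. Folds where the discovered rule leaves
fewer than 5 members in either class are dropped with a warning and
enumerated in the diagnostics rather than failing the run.

**Pooling.** Fold-specific rules differ, so the pooled estimand is membership
in the **union** of the fold rules versus its complement. Per contributing
fold the nuisance models are refit on the parameter-generating sample with
the union indicator (a propensity model fit for one rule cannot emit
probabilities for another) using a single shared outcome scale, the
estimation-sample predictions are stacked across folds, and one fluctuation
is fit on the stack; `psi` and its standard error come from the stacked EIC.

**Per-component thresholds.** The same backfitting is run with `f`
restricted to single-variable trees on one exposure; the selected tree's
split values become cutpoints, harmonized across folds by their union. Each
non-reference level is contrasted against the lowest level only — rows in
intermediate levels are excluded from that contrast — and the per-level
results are pooled across folds as above. All contrasts are reported without
multiplicity adjustment; the output records how many were made.

## What the simulator states, and what a green test establishes

The bundled simulator is the package's entire evidence base, so its
assumptions are worth stating plainly. Covariates are independent standard
normals. Exposure `j` is `alpha * c_j' W + Uniform(0, 1.5)` with unit-norm
loadings `c_j` drawn deterministically from the seed and
`alpha = confounding_strength`. A continuous outcome is
`tau * 1{A in region} + beta' W + N(0, noise_sd^2)` with
`beta = alpha * b`; the binary outcome passes the same linear predictor
through a logistic link. Because the region indicator enters additively, the
true ATE of the region is exactly `tau` at any confounding strength, while
the unadjusted difference in means is biased whenever `alpha > 0` — which is
what makes the debiasing property testable.

Numerical choices worth recording:

* **Exposure support `Uniform(0, 1.5)`.** The interaction presets fix the
  effect region at `a1 > 0.5 & a2 > 0.5`. The support is chosen so that this
  region is the *minority* "exposed" group (prevalence 0.44): if the region
  covered most of the space, the leaf with the largest partial-residual
  contrast would provably be a complement leaf and the designated rule would
  invert. It also keeps the 1-d threshold at 1.0 used in the component
  scenarios interior to the support.
* **Confounded preset strength 1.** At strength 0.5 the unadjusted bias
  (−0.18) is only about twice the sampling error of a difference in means at
  the design `n = 500`, i.e. the scenario barely instantiates confounding;
  at strength 1 the bias (−0.56) is roughly six times the sampling error.
* **The truth oracle** computes the ATE of an arbitrary box rule — or a
  union of boxes, via inclusion–exclusion — by g-computation: conditional
  box probabilities given `W` are analytic (shifted uniforms), and only the
  outer expectation over `W` is Monte Carlo. The expectation is restricted
  to the covariate positivity region (`0 < P(rule|W) < 1`); under strong
  confounding the rule box can be impossible for some `W`, where the
  contrast is undefined — the propensity-truncated TMLE estimates the
  positivity-restricted estimand.

What a green suite does **not** establish: the simulator's exposures are
conditionally independent given `W` with uniform marginals, its confounding
is linear, and its effect regions are axis-aligned boxes. Real exposure data
have correlated, skewed components, nonlinear confounding and effect regions
that need not be rectangular; performance there is a scientific question, not
a software property. The suite establishes that the machinery is correct in
a world where the truth is known.

## Defaults at a glance

| Parameter | Default | Why |
|---|---|---|
| outer folds `V` | 5 | inference needs moderately sized estimation samples |
| inner CV folds | 5 | smaller than outer V to bound compute |
| tree depths | 1–3 | interpretability and positivity degrade with depth |
| min leaf fractions | 0.05, 0.1 | leaves must be estimable subgroups |
| `min_support` | 0.05 | designated rule must cover ≥ 5% of the sample |
| `g_bounds` | (0.025, 0.975) | propensity truncation |
| backfit `tol` | `1e-3 * sd(Y)` | scale-free convergence criterion |
| backfit `max_iter` | 10 | backfitting converges in a few passes |
| outcome scaling pad | 10% of range | reduces clipping of estimation-sample Y |

## Known limitations

* No missing-data handling beyond complete-case deletion, no survey weights,
  no clustered or longitudinal data, no survival outcomes.
* No cost-complexity pruning or oblique splits; the tree grid is deliberately
  shallow.
* The union-rule pooling is one defensible reading of "pooled results";
  fold-specific results are always reported alongside it.
* **The union estimand leaks at the boundary.** The union rule is adapted to
  every observation: each fold's thresholds are gap midpoints avoiding its
  parameter-generating sample, and every estimation point belongs to the
  parameter-generating samples of the other folds. The thin band between the
  union boundary and the true effect region therefore contains essentially no
  observed data in *any* estimation sample, so no estimator built from the
  same n points can register its (nonzero) population measure. The pooled
  point estimate consequently carries an O(1/n) discrepancy from the
  union-rule population truth; when the outcome noise is very small this
  discrepancy can exceed the O(1/√n) standard error and intervals for the
  pooled estimand undercover (in the interaction preset at n = 500, noise sd
  0.2: bias ≈ +0.03 against se ≈ 0.02, coverage 0.84). Fold-specific
  estimands do not leak — each fold's rule is discovered without its
  estimation sample — and show nominal behavior (bias ≈ 0.001, coverage
  0.93 over the same runs; asserted in the test suite). Interpret the pooled
  row as a precision-weighted summary, and the fold rows as the
  honestly-calibrated inference.
* Confidence intervals are per-contrast normal intervals; the number of
  contrasts is reported but not adjusted for.

## A worked example

```{r example, eval = FALSE}
cfg <- preset_config("interaction-2d", n = 500, seed = 3)
sim <- simulate_mixtures(cfg)
res <- mixtree(sim$data, mixtree_config(V = 5, seed = 3))
print(res)
```

See the README for the printed output of this exact run.
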