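---
title: "Power analysis for linear hypotheses in MML-estimated IRT models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for linear hypotheses in MML-estimated IRT models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmlpower)
```

## The model and the hypotheses

The package works with unidimensional IRT models under local independence:
each person draws a latent trait $\theta$ from a population distribution
$\Phi$ (standard normal by default) and answers the $I$ items independently
given $\theta$. Two response-function families are supported, both in the
slope/intercept parametrization:

* the two-parameter logistic (2PL) for dichotomous items,
  $P(x_i = 1 \mid \theta) = \mathrm{logit}^{-1}(a_i\theta + d_i)$, with the
  Rasch model as its equal-slopes special case;
* the generalized partial credit model (GPCM) for $K$ ordered categories,
  $P(x_i = k \mid \theta) \propto \exp\{(k-1)a_i\theta + d_{ik}\}$ with
  $d_{i1} = 0$ for identification, with the partial credit model (PCM) as
  its equal-slopes special case;

plus a two-group layout for differential item functioning (DIF) in which the
first item's $(a, d)$ pair is duplicated per group and the remaining items
are shared anchors.

All item parameters are stacked into a single vector $\beta$ with a frozen
interleaved order ($a_1, d_1, a_2, d_2, \dots$; group-specific item-1 slots
first in the DIF layout). Hypotheses are linear constraints $A\beta = c$
with full-row-rank $A$; the row count is the degrees of freedom of all four
tests. Restricted models (Rasch, PCM) are represented in the *full*
parameter space via the equality constraints rather than in a reduced
space, so design matrices, information matrices, and every statistic live
in one coordinate system.

## Expected noncentrality parameters

Under marginal estimation, the data for $n$ persons are an i.i.d. sample
from the multinomial over response patterns with probabilities
$g_\beta(x) = \int f_{\beta,\theta}(x)\,\Phi(\theta)\,d\theta$. Under the
null the Wald, LR, score, and gradient statistics are asymptotically
central $\chi^2_{df}$; under a local alternative they are noncentral with a
noncentrality obtained by evaluating each statistic at the population
parameters — pattern frequencies replaced by $n\,g_\beta(x)$, covariance
matrices by the inverse expected Fisher information
$I_F(\beta,1) = -\sum_x \ddot l_\beta(x)\, g_\beta(x)$. Because the
information is proportional to $n$, every noncentrality factorizes as
$\lambda(\beta, n) = n\,\lambda(\beta, 1)$, and power analysis reduces to
one evaluation of $\lambda(\beta, 1)$ per statistic followed by noncentral
$\chi^2$ arithmetic (`power_at_n()`, `required_sample_size()`).

Two ingredients deserve comment.

**Expected restricted parameters.** The LR, score, and gradient
noncentralities need $\beta_r$, the null-constrained parameter set that the
restricted-model ML estimator converges to when the alternative $\beta$
generates the data: the maximizer of
$\sum_x \log g_{\beta_0}(x)\, g_\beta(x)$ over $\{\beta_0 : A\beta_0 = c\}$.
`restricted_parameters()` solves this by reparametrizing the constraint set
as $\beta_0 = \beta_\perp + N\gamma$ (orthonormal null-space basis $N$ of
$A$, $\beta_\perp$ the projection of the alternative onto the set) and
running BFGS with analytic gradients on $\gamma$. The projection start is
already close to the optimum in all tested configurations; convergence is
declared at a projected gradient below $10^{-6}$ (typically $10^{-8}$ is
reached). When $\beta$ already satisfies the null, it is returned unchanged
and all four noncentralities short-circuit to zero.

**The gradient statistic and the sign of the multipliers.** The gradient
statistic needs the Lagrange multipliers of the restricted optimum. At an
interior constrained maximum the expected score
$\bar s = \sum_x \dot l_{\beta_r}(x) g_\beta(x)$ lies in the row space of
$A$, and the package solves $\bar s = A'k$, which makes
$\lambda_4 = k'(A\beta - c)$ identical to $\bar s'(\beta - \beta_r)$ —
score-at-restricted times parameter displacement, the orientation under
which the statistic is asymptotically nonnegative and first-order equal to
the other three. The solve is a least-squares solution through the normal
equations of $A$; a residual above tolerance flags a non-converged
restricted solution rather than silently producing a meaningless value.

### Numerical choices

* **Quadrature.** Gauss–Hermite with 61 nodes, transformed to the normal
  latent distribution and renormalized. This makes ten-item marginal
  probabilities accurate to roughly $10^{-10}$; the unit-test oracles use
  adaptive integration (`stats::integrate`) and fine trapezoid grids
  precisely so that the quadrature is independently checked.
* **Derivatives.** Gradients of $\log g_\beta(x)$ are analytic
  (posterior-weighted complete-data scores, fully vectorized over patterns
  and nodes). The expected information offers two routes: finite
  differences of the analytic score (the defining Hessian expectation) and
  the score outer-product identity, which is exact here because the
  expectation is taken at the same $\beta$; the two agree to $10^{-4}$ and
  the cheaper outer-product form is used in iterative contexts.
* **Pattern-space gate.** The analytical path enumerates all $K^I$
  patterns and refuses beyond $2\times 10^6$ (e.g. 21+ dichotomous items),
  pointing to the sampling path instead. Information matrices inside the
  observed statistics fall back from exact enumeration to the empirical
  score cross-product above $2^{15}$ pattern rows; both estimates converge
  to the expected information.
* **Degenerate inputs.** Noncentralities are clamped at zero with a
  warning below $-10^{-10}$; a singular information matrix reports its
  smallest eigenvalue (the typical cause is an unidentified layout — e.g. a
  two-item 2PL has 4 parameters but only 3 pattern degrees of freedom, so
  Wald/score quantities are undefined there); rank-deficient hypothesis
  matrices are rejected at construction because they would silently corrupt
  the degrees of freedom.

## MML fitting and observed statistics

The sampling-based path and any simulation validation need actual fits.
`fit_mml()` maximizes the pattern-collapsed marginal log-likelihood
$\sum_x h(x) \log g_\beta(x)$ — exactly equal to the row-wise likelihood,
and far cheaper since only distinct observed patterns enter — by BFGS with
the same analytic gradients, capped at 5000 iterations. We chose direct
quasi-Newton over an EM loop deliberately: with analytic marginal gradients
and collapsed patterns each iteration is cheap, and the score statistics
require tight score norms at the optimum that quasi-Newton reaches in tens
of iterations. Constrained (restricted) fits reuse the null-space
parametrization, so nested fits differ only in the coordinate system
searched. Starting values are neutral (unit slopes, logit of observed
proportions as intercepts), and the restricted fit starts from the
unrestricted estimate when available.

The observed Wald and score statistics require an information estimate at
the estimates; the package evaluates the *expected* Fisher information at
the estimated parameters (exact over the enumerable pattern space, the
empirical cross-product otherwise). Any consistent estimate works for the
asymptotics; this choice is deterministic and oracle-checkable. The
gradient statistic needs no information matrix at all, which is its
practical appeal.

`sampling_ncp()` implements the large-sample approximation: draw one
artificial dataset of size $n_{\mathrm{art}}$ from the alternative, fit
restricted and unrestricted models, compute the statistics, and take
$(\mathrm{statistic} - df)/n_{\mathrm{art}}$, clamped at zero. The Monte
Carlo standard deviation of the resulting $\hat\lambda(\beta,1)$ scales as
$\sqrt{2(df + 2n_{\mathrm{art}}\lambda)}/n_{\mathrm{art}}$, i.e. a
percent-level relative error at $n_{\mathrm{art}} = 10^6$ for typical
effect sizes — visible when comparing to the analytical path, and the reason
the analytical path is preferred whenever the pattern space is enumerable.

## What the synthetic-data generator emulates

`simulate_responses()` draws traits from $\Phi$ (per group in the DIF
layout) and responses item-wise given the trait — the models' own
data-generating process, including local independence. The condition
system (`sim_condition()`, `draw_condition_parameters()`, `sim_grid()`)
reproduces a 180-cell validation design: three hypothesis types, item
counts 5/10/20/50, sample sizes 100–3000, and three effect sizes. Effect
recipes: intercepts standard normal; slopes lognormal with natural-scale
mean 1 and SDs of 0.22/0.17/0.12/0.10 (large) or 0.16/0.12/0.08/0.05
(small) for 5/10/20/50 items — the SD shrinks with the item count because
slope heterogeneity becomes easier to detect, keeping power away from 1;
DIF fixes item 1 at $(1.125, 0.125)$ vs $(0.875, -0.125)$ for the small
and group differences of 0.5 in both parameters for the large effect, with
anchor slopes lognormal (SD 0.1). "Lognormal with mean 1 and SD $s$" is
read on the natural scale, with the underlying normal moments solved from
the moment equations — the conventional reading of the phrase. The
polytomous conditions reuse the dichotomous slope SDs. Per-condition seeds
are derived deterministically from the condition label, so the whole grid
is reproducible without stored fixtures.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: multidimensional or non-normal trait
distributions, local dependence, guessing (3PL-type lower asymptotes,
whose boundary parameters break the central-$\chi^2$ null for all but the
score test), missingness, and unequal group sizes beyond the configurable
weights. The equal group split in the DIF layout is a symmetric default,
not an empirical claim.

## Design choices on genuinely open points

* The DIF group split defaults to 50/50 (configurable via
  `group_weights`); observed fits use the observed group proportions.
* $\alpha$ defaults to .05 and target power to .9 throughout.
* Required sample sizes are reported as integer ceilings (persons), with a
  $\pm 1$ verification step against the power function to absorb CDF
  roundoff at the boundary.
* `c` is stored explicitly in hypotheses even though the built-in
  constructors all use $c = 0$, to keep user-defined affine hypotheses
  first-class.
* The stationarity system for the multipliers is solved with $A'k$ on the
  right-hand side (see above); the alternative sign convention yields the
  negated statistic and is rejected by the nonnegativity and
  first-order-equivalence properties that the test suite enforces.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run at sizes a reviewer can
re-execute while still exercising every code path: full enumeration up to
$2\times 2^{10}$ pattern rows (the two PISA clusters and the two-group DIF
model), parameter recovery at $n = 10^5$, the sampling path at
$n_{\mathrm{art}} \le 10^6$, and a 1000-replication null calibration at
$n = 3000$ with five items. The validation grid ships as an example script
(`inst/examples/sim_grid_runner.R`) with a reduced replication count; the
per-cell machinery is identical at any replication count.

## Known limitations

* The analytical path is exponential in the number of items; beyond the
  enumeration gate only the sampling path is available, inheriting
  percent-level Monte Carlo error.
* The asymptotic noncentral-$\chi^2$ description degrades at small $n$ and
  large effects (the statistics differ from their expectation most visibly
  below $n \approx 250$); the same caveat applies to the central-$\chi^2$
  null calibration itself, which the shipped null-calibration check makes
  visible (slightly conservative rejection rates at five items).
* Hypotheses on person-distribution parameters (e.g. group trait means)
  and 3PL/multidimensional templates are out of scope.
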