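---
title: "Robust mediation analysis with a data-driven Huber tuning constant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust mediation analysis with a data-driven Huber tuning constant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remed)
```

## The model

The simple mediation model relates an independent variable $X$, a mediator
$M$ and an outcome $Y$ through three linear equations:

$$Y = i_1 + cX + e_1, \qquad
  M = i_2 + aX + e_2, \qquad
  Y = i_3 + c'X + bM + e_3.$$

Here $c$ is the total effect of $X$ on $Y$, $c'$ the direct effect after
adjusting for the mediator, and the indirect effect transmitted through
$M$ is measured either by the product $ab$ or the difference $c - c'$.
Under least squares the two coincide; for robust losses they differ in
general, and the product form is the more efficient one, so inference in
this package centres on $ab$. When the errors are independent and
symmetric with a unique median at zero, the population identity
$c = c' + ab$ holds, which the test suite verifies on simulated data.

Ordinary least squares is efficient under normal errors but degrades
badly under heavy tails or outlying responses; least absolute deviation
is robust but wasteful under normality. The package estimates each
equation by M-regression: coefficients minimize
$\sum_i \rho(r_i/\hat\sigma)$ for a loss $\rho$, with the Huber loss

$$\rho_k(u) = \begin{cases} u^2/2, & |u| \le k \\
  k|u| - k^2/2, & |u| > k \end{cases}$$

as the primary choice. Its influence curve $\psi_k$ is the identity
clipped to $[-k,k]$: observations with standardized residuals inside the
window are treated quadratically (as in least squares), larger ones only
linearly. The constant $k$ trades efficiency against robustness; the
conventional $k = 1.345$ gives 95% efficiency under normal errors. The
residual scale $\hat\sigma$ is the median absolute deviation times
$1/\Phi^{-1}(3/4) \approx 1.4826$, which is consistent for the standard
deviation under normality and resistant to the same outliers the loss
protects against.

## Estimation

Each equation is fitted by iteratively reweighted least squares: given
current residuals, the scale is re-estimated by MAD, weights
$w_i = \psi_k(r_i/\hat\sigma)/(r_i/\hat\sigma)$ are formed, and a
weighted least-squares problem is solved, until the maximum relative
coefficient change drops below $10^{-8}$ (at most 200 iterations). Two
starting points are used — the OLS solution and an LAD approximation
reached by a short LAD-weighted run from it — and the fit with the
smaller objective wins; this guards against multiple local minima
without a material cost. With the scale frozen within an iteration the
weighted-LS step cannot increase the Huber objective (the weights define
a quadratic majorant), and any numerical violation beyond $10^{-10}$ is
surfaced as a warning.

Degenerate inputs are kept well-defined: if the MAD of the residuals
hits zero with all residuals zero, the interpolating fit is returned as
converged; if it is zero with nonzero residuals (more than half the
responses identical), the scale falls back to the mean absolute residual
times $\sqrt{\pi/2}$, its normal-consistent counterpart. The scale may
also be frozen at its OLS value (`scale = "fixed"`) since the
alternation of scale and coefficients is a modelling choice rather than
a mathematical necessity; the iterated MAD is the default because it is
the standard robust-regression practice.

## Choosing the tuning constant from data

The asymptotic covariance of the M-estimator is $\tau^2(k)\,W^{-1}$ with
the efficiency factor

$$\tau^2(k) = \frac{E[\psi_k^2(e/\sigma)]}{(E[\psi_k'(e/\sigma)])^2},$$

so the best $k$ for a given error law minimizes $\tau^2(k)$. As
$k \to \infty$, $\tau^2 \to \mathrm{Var}(e)$ (the least-squares limit);
as $k \to 0$, $\tau^2 \to 1/(4f(0)^2)$ (the least-absolute-deviation
limit). For a known error density `analytic_tau2()` evaluates the factor
by adaptive quadrature on $[-k, k]$ (the integrand is smooth there; the
kink of $\psi$ sits on the boundary, and the tail contribution
$k^2 P(|e| > k)$ is available from the CDF), and `optimal_k_analytic()`
minimizes it over a grid.

With real data the error law is unknown, so the factor is estimated
nonparametrically from standardized residuals,

$$\hat\tau^2(k) = \frac{n^{-1}\sum_i \psi_k^2(r_i/\hat\sigma)}
  {\bigl[n^{-1}\sum_i 1\{|r_i/\hat\sigma| \le k\}\bigr]^2},$$

and minimized over the grid $k = 0.01, 0.02, \ldots, 3$. The ceiling
$K = 3$ reflects that standardized normal errors fall inside $[-3,3]$
with probability 99.73%, so larger constants change nothing materially;
the 0.01 step makes the grid discretization error negligible. Selection
runs once per equation (initial fit at $k = 1.345$, selection, one
refit); the three equations have three error laws, so each gets its own
constant. `refine_rounds` exposes further alternation, which in our
experience changes the selection rarely and is off by default.

Two stability rules matter in practice:

* **Minimum effective sample per grid point.** The denominator of
  $\hat\tau^2(k)$ counts residuals inside $[-k,k]$. At tiny $k$ that
  count is a handful of observations, its relative noise is large, and
  because a minimum is taken over hundreds of grid points, the noise
  systematically produces spurious minima at tiny $k$ — at $n = 200$
  under normal errors the unguarded selector picks a median $k$ near
  0.1, costing roughly 40% efficiency against least squares. Grid points
  where fewer than half the residuals fall inside the window
  (`min_prop_inside = 0.5`) are therefore excluded. The bound has a
  direct interpretation: treating more than half the sample as outlying
  contradicts the premise that outliers are a minority, and with at
  least $n/2$ points inside, the denominator's relative noise is at most
  about $\sqrt{2/n}$. With the guard the selector tracks the analytic
  optimum (e.g. median $\hat k \approx 1.2$ at $n = 10^4$ for the
  contaminated normal whose optimum is 1.32) and its spread shrinks with
  $n$. Remaining grid points with an empty window are excluded as
  undefined rather than treated as infinite minima.
* **Small-sample fallback.** Below `min_n_for_selection = 30`
  observations (or when fewer than two grid points survive), selection
  noise makes the selected-$k$ Sobel test anti-conservative, and the fit
  keeps the moderate conventional constant $k = 1.345$ with
  `fallback_used = TRUE`.

Ties on the $\hat\tau^2$ curve — exact ties occur on the flat segment
beyond the largest standardized residual — are broken toward the largest
minimizing $k$, which preserves efficiency near the normal model.

## Inference on the indirect effect

Standard errors come from the sandwich form
$\hat\sigma^2\hat\tau^2(k)(X^\top X)^{-1}\,n/(n-p)$, with the
loss-matched factor: $\hat\tau^2$ at the fitted $k$ for Huber, the
sample variance of standardized residuals for LS, and
$1/(4\hat f(0)^2)$ with a kernel density estimate at zero for LAD. Four
interval constructions are available for $ab$:

* **Robust Sobel** — delta-method SE
  $\sqrt{\hat b^2 se_a^2 + \hat a^2 se_b^2}$ and a normal interval. The
  second-order variant (adding $se_a^2 se_b^2$) is exposed via
  `variant = "second"`; the first-order form is the default as the
  classical Sobel construction.
* **Monte-Carlo distribution of the product** — quantiles of
  $a^* b^*$ with $a^*, b^*$ drawn from normals centred at the estimates,
  respecting the product's non-normal shape when the paths are small.
* **Percentile bootstrap (PRCT)** and **BCa** — case resampling of the
  rows (x, m, y and covariates jointly), refitting the model on each
  resample. The tuning constant is re-selected inside each resample by
  default, so selection noise honestly propagates into the interval;
  `k_fixed_in_bootstrap = TRUE` freezes the full-data selection (the
  full-data median of the three per-equation constants) for users who
  prefer the selection conditioned on. BCa adjusts the quantile
  positions with a bias-correction $z_0$ (ties half-counted) and a
  jackknife acceleration. Rank-deficient resamples are redrawn, with an
  abort once redraws exceed 10% of `B`.

The difference estimator $\hat c - \hat c'$ is available through the
bootstrap only (`statistic = "difference"`): the delta-method Sobel
construction is specific to the product form, and the product is the
more efficient estimator anyway.

## What the simulation harness emulates

`mediation_design()` fixes the study conditions: data are generated from
the structural direction $M = aX + e_2$, $Y = c'X + bM + e_3$ with
standard-normal $X$, zero intercepts, and i.i.d. errors from one of four
symmetric families — standard normal, Laplace(0,1), the contaminated
normal $0.9\,N(0,1) + 0.1\,N(0,25)$, and Student-$t$ (df 3 or 5).
Conventional small/medium effect sizes (0.14, 0.39) and sample sizes
(50, 100, 200) are the defaults, with 1,000 replications per setting;
the heavier bootstrap-within-simulation studies in the tests and the
acceptance script run 500 replications with $B = 500$, a deliberate
scale-down that leaves the binomial noise of a rejection rate near
$\pm 1$ percentage point. All replication-level seeds derive
deterministically from the design seed, so a summary is bit-reproducible
from its design.

What the generator does **not** emulate: leverage points in the design
(the method protects against outlying responses, not outlying
regressors, and the model assumes well-behaved $X$), skewed errors
(Theorem-level consistency of $c = c' + ab$ needs symmetry), dependent
or heteroscedastic errors, and measurement error in $M$. Passing tests
therefore speak to response-outlier robustness under symmetric noise,
not to these other departures.

## Numerical choices and limitations

* LAD weights $1/|u|$ are capped at $10^6$ near zero residuals, the
  standard IRLS regularization; the LAD fit is therefore a smooth
  approximation whose objective may exceed the exact LAD minimum by a
  negligible amount.
* The large-$k$ limit $\tau^2 \to \mathrm{Var}(e)$ is approached at a
  rate governed by the tails: by $k = 10$ for Gaussian-tailed families
  but only as $O(1/k)$ for $t(3)$, so numerical checks of the limit use
  proxies scaled to the tail weight.
* Monte-Carlo and bootstrap intervals take mandatory seeds and record
  them in their results; `run_analysis()` reports will reproduce
  byte-for-byte given the same configuration.
* The Student-$t$ family with df $\le 2$ has infinite variance: the
  distribution object reports `variance = Inf` and the least-squares
  limit diverges, while $\tau^2(k)$ itself stays finite for every finite
  $k$ — one more reason a bounded influence curve helps there.
* Inference treats the selected $k$ as fixed when forming the Sobel SE;
  at small $n$ the selection noise (an optimizer's-curse effect) makes
  that SE slightly optimistic, which is exactly why the small-sample
  fallback and the per-resample re-selection inside the bootstrap exist.

## A worked example

```{r example}
set.seed(1)
d <- mediation_design(a = 0.39, b = 0.39, n = 500,
                      error_dist = "student_t", seed = 1)
dat <- gen_mediation_data(d, 1)
fit <- fit_mediation_auto(dat$x, dat$m, dat$y)
fit
se <- mediation_se(fit)
sobel_ci(fit$a, fit$b, se$se_a, se$se_b)
mc_product_ci(fit$a, fit$b, se$se_a, se$se_b, seed = 2)
bootstrap_ci(dat$x, dat$m, dat$y, B = 1000, seed = 3, method = "bca")
```

The selected constants sit well below the grid ceiling for these
heavy-tailed errors, and the robust intervals exclude zero, as they
should with a true indirect effect of $0.39^2 \approx 0.152$.
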