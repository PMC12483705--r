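# remed — robust and efficient mediation analysis via the Huber loss

Mediation analysis asks how much of the effect of an independent variable
`X` on an outcome `Y` travels through an intermediate variable `M`. The
simple mediation model is three linear equations,

    Y = i1 + c X + e1
    M = i2 + a X + e2
    Y = i3 + c'X + b M + e3,

and the indirect effect is the product `ab` (equivalently, under least
squares, the difference `c − c'`). Least-squares estimation is standard
but fragile: psychological, epidemiological and social-science data are
routinely heavy-tailed or contaminated by outlying responses, and then
the LS estimate of `ab` can be badly inefficient, while the
least-absolute-deviation (LAD) alternative wastes efficiency when the
data are in fact well behaved.

`remed` estimates each equation by M-regression with the **Huber loss**

    rho_k(u) = u^2/2           if |u| <= k
               k|u| - k^2/2    otherwise,

fitted by iteratively reweighted least squares with a MAD residual scale
and multiple starting points. The tuning constant `k` — the boundary
between quadratic (LS-like) and linear (LAD-like) treatment of
standardized residuals — is **selected from the data** by minimizing a
nonparametric estimate of the asymptotic-variance factor

    tau^2(k) = E[psi_k^2(e/sigma)] / (E[psi_k'(e/sigma)])^2

over the grid k = 0.01, …, 3, independently for each equation. The
package provides robust Sobel, Monte-Carlo distribution-of-the-product,
percentile-bootstrap and BCa confidence intervals for `ab`, plus a
simulation harness that compares LS, LAD and Huber estimators by MSE,
type-I error and power under normal, Laplace, contaminated-normal and
Student-t errors. It is aimed at applied researchers who want mediation
inference that survives non-normal data, and at methodologists studying
robust indirect-effect estimation.

## A worked example

```r
library(remed)
set.seed(1)
d <- mediation_design(a = 0.39, b = 0.39, n = 500,
                      error_dist = "student_t", seed = 1)
dat <- gen_mediation_data(d, 1)

fit <- fit_mediation_auto(dat$x, dat$m, dat$y)
fit
#> <mediation_fit>
#>    a = 0.43007  b = 0.39486  c = 0.09203  c' = -0.078689
#>    indirect effect: product = 0.16982, difference = 0.17072
#>   selected k: total = 0.87, mediator = 0.71, outcome = 0.81

se <- mediation_se(fit)
sobel_ci(fit$a, fit$b, se$se_a, se$se_b)
#> <interval_estimate> sobel_normal 95%: [0.119897, 0.219735]
mc_product_ci(fit$a, fit$b, se$se_a, se$se_b, seed = 2)
#> <interval_estimate> monte_carlo 95%: [0.122355, 0.222185]
bootstrap_ci(dat$x, dat$m, dat$y, B = 1000, seed = 3, method = "bca")
#> <interval_estimate> bca 95%: [0.121086, 0.228424]
```

The errors here are t(3), so the data-driven constants land well below
the grid ceiling (0.7–0.9: roughly a fifth of the observations are
treated linearly), and all three intervals comfortably exclude zero —
the true indirect effect is 0.39² ≈ 0.152. Under well-behaved normal
errors the selected constants instead drift toward the ceiling and the
fit reproduces least squares.

Analyses of tabular files, simulation grids and τ̂²(k) curves are also
available from the shell through the thin CLI in `inst/cli/remed.R`:

```sh
Rscript inst/cli/remed.R fit --input data.csv --x X --m M --y Y \
    --loss huber --k auto --ci sobel,mc,prct,bca --seed 1 --out report.json
Rscript inst/cli/remed.R simulate --config scenarios.yaml --out results/
```

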