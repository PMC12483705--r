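new_interval <- function(lower, upper, level, method, n_resamples = 0L,
                         seed = NA_integer_, extra = list()) {
  stopifnot(lower <= upper)
  structure(c(list(lower = lower, upper = upper, level = level,
                   method = method, n_resamples = n_resamples, seed = seed),
              extra),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("<interval_estimate> %s %g%%: [%.6g, %.6g]\n",
              x$method, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

.check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1", call. = FALSE)
  invisible(level)
}

#' Robust sandwich covariance of an M-regression fit
#'
#' Asymptotic covariance of the coefficients,
#' \eqn{\hat\sigma^2 \hat\tau^2(k) (X^\top X)^{-1} \, n/(n-p)},
#' where \eqn{\hat\tau^2} is the loss-specific efficiency factor
#' estimated from the standardized residuals: [empirical_tau2()] at the
#' fit's `k` for the Huber loss, the sample variance of the standardized
#' residuals for LS, and \eqn{1/(4\hat f(0)^2)} with a kernel density
#' estimate at zero for LAD. The factor `n/(n-p)` is a finite-sample
#' degrees-of-freedom correction.
#'
#' @param fit an `irls_fit`.
#' @return list of class `covariance_estimate` with `matrix` (p x p),
#'   `tau2_used`, `scale_used`.
#' @export
robust_vcov <- function(fit) {
  stopifnot(inherits(fit, "irls_fit"))
  X <- fit$design
  n <- fit$n
  p <- ncol(X)
  if (n <= p) stop("need n > p for a covariance estimate", call. = FALSE)
  s <- fit$scale
  if (s <= 0)
    stop("degenerate fit (zero residual scale); covariance undefined",
         call. = FALSE)
  u <- fit$residuals / s
  tau2 <- switch(fit$loss$name,
    huber = empirical_tau2(fit$residuals, fit$loss$k, s),
    ls = var(u),
    lad = {
      f0 <- .density_at_zero(u)
      1 / (4 * f0^2)
    })
  if (!is.finite(tau2))
    stop("efficiency factor undefined: all standardized residuals exceed k",
         call. = FALSE)
  xtx_inv <- tryCatch(solve(crossprod(X)),
                      error = function(e)
                        stop("singular design cross-product", call. = FALSE))
  structure(list(matrix = s^2 * tau2 * xtx_inv * n / (n - p),
                 tau2_used = tau2, scale_used = s),
            class = "covariance_estimate")
}

.density_at_zero <- function(u) {
  d <- density(u, n = 512)
  f0 <- stats::approx(d$x, d$y, xout = 0, rule = 2)$y
  max(f0, .Machine$double.eps)
}

#' Robust Sobel statistic for the indirect effect
#'
#' First-order delta-method standard error of the product
#' \eqn{\hat a \hat b},
#' \eqn{se_{ab} = \sqrt{\hat b^2 se_a^2 + \hat a^2 se_b^2}}, and the
#' corresponding z statistic. The `"second"` variant adds the
#' second-order term \eqn{se_a^2 se_b^2} under the square root.
#'
#' @param a_hat,b_hat path-coefficient estimates.
#' @param se_a,se_b their standard errors.
#' @param variant `"first"` (default) or `"second"` order form.
#' @return list with `z` and `se_ab`.
#' @export
sobel_statistic <- function(a_hat, b_hat, se_a, se_b,
                            variant = c("first", "second")) {
  variant <- match.arg(variant)
  stopifnot(se_a >= 0, se_b >= 0)
  v <- b_hat^2 * se_a^2 + a_hat^2 * se_b^2
  if (variant == "second") v <- v + se_a^2 * se_b^2
  se_ab <- sqrt(v)
  if (se_ab == 0 && a_hat * b_hat != 0)
    stop("degenerate inference: zero SE with a nonzero indirect effect",
         call. = FALSE)
  z <- if (se_ab == 0) 0 else (a_hat * b_hat) / se_ab
  list(z = z, se_ab = se_ab)
}

#' Normal-based Sobel confidence interval
#'
#' \eqn{\hat a \hat b \pm z_{\alpha/2} \, se_{ab}} with the
#' delta-method standard error of [sobel_statistic()].
#'
#' @inheritParams sobel_statistic
#' @param level confidence level in (0, 1).
#' @return an `interval_estimate` with method `"sobel_normal"`.
#' @export
sobel_ci <- function(a_hat, b_hat, se_a, se_b, level = 0.95,
                     variant = c("first", "second")) {
  .check_level(level)
  st <- sobel_statistic(a_hat, b_hat, se_a, se_b, variant = variant)
  ab <- a_hat * b_hat
  zq <- qnorm(1 - (1 - level) / 2)
  new_interval(ab - zq * st$se_ab, ab + zq * st$se_ab, level,
               "sobel_normal", extra = list(z = st$z, se_ab = st$se_ab))
}

#' Monte-Carlo distribution-of-the-product confidence interval
#'
#' Simulates \eqn{a^* \sim N(\hat a, se_a^2)} and
#' \eqn{b^* \sim N(\hat b, se_b^2)} independently and takes empirical
#' quantiles of \eqn{a^* b^*}. This respects the non-normal shape of the
#' product distribution when the coefficients are small relative to
#' their SEs.
#'
#' @inheritParams sobel_ci
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed for the draws.
#' @return an `interval_estimate` with method `"monte_carlo"`.
#' @export
mc_product_ci <- function(a_hat, b_hat, se_a, se_b, level = 0.95,
                          n_draws = 1e5, seed = 1L) {
  .check_level(level)
  stopifnot(se_a >= 0, se_b >= 0, n_draws >= 1)
  if (n_draws < 1000)
    warning("fewer than 1000 Monte-Carlo draws; quantiles will be noisy",
            call. = FALSE)
  if (se_a == 0 && se_b == 0) {
    ab <- a_hat * b_hat
    return(new_interval(ab, ab, level, "monte_carlo",
                        n_resamples = as.integer(n_draws), seed = seed))
  }
  set.seed(seed)
  prod_draws <- rnorm(n_draws, a_hat, se_a) * rnorm(n_draws, b_hat, se_b)
  alpha <- 1 - level
  qs <- quantile(prod_draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  new_interval(qs[1], qs[2], level, "monte_carlo",
               n_resamples = as.integer(n_draws), seed = seed)
}

.default_loss_options <- function() {
  list(loss = "huber", k = "auto", grid = default_k_grid(),
       min_n_for_selection = 30L, fallback_k = 1.345,
       min_prop_inside = 0.5, k_fixed_in_bootstrap = FALSE,
       tol = 1e-8, max_iter = 200L)
}

.resolve_loss_options <- function(loss_options) {
  opts <- .default_loss_options()
  if (!is.null(loss_options)) {
    bad <- setdiff(names(loss_options), names(opts))
    if (length(bad))
      stop("unknown loss option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    opts[names(loss_options)] <- loss_options
  }
  if (!opts$loss %in% .loss_names)
    stop("'loss' must be one of huber, ls, lad", call. = FALSE)
  opts
}

.fit_with_options <- function(x, m, y, covariates, opts) {
  if (opts$loss == "huber" && identical(opts$k, "auto")) {
    fit_mediation_auto(x, m, y, covariates, grid = opts$grid,
                       min_n_for_selection = opts$min_n_for_selection,
                       fallback_k = opts$fallback_k,
                       min_prop_inside = opts$min_prop_inside,
                       tol = opts$tol, max_iter = opts$max_iter)
  } else {
    k <- if (opts$loss == "huber") as.numeric(opts$k) else 1.345
    fit_mediation(x, m, y, covariates,
                  loss = loss_spec(opts$loss, k = k),
                  tol = opts$tol, max_iter = opts$max_iter)
  }
}

#' Bootstrap confidence intervals for the indirect effect
#'
#' Case bootstrap: rows `(x, m, y, covariates)` are resampled jointly
#' with replacement and the mediation model is refitted on each
#' resample; the statistic is the product estimator \eqn{\hat a \hat b}
#' (or the difference \eqn{\hat c - \hat c'} with
#' `statistic = "difference"`). For the Huber loss with `k = "auto"` the
#' tuning constant is re-selected within each resample by default so
#' that selection noise propagates into the interval; set
#' `loss_options$k_fixed_in_bootstrap = TRUE` to freeze the full-data
#' selection. Rank-deficient resamples are redrawn (at most 10\% of `B`
#' before aborting).
#'
#' Methods: `"prct"` takes empirical \eqn{\alpha/2} and
#' \eqn{1-\alpha/2} quantiles of the bootstrap distribution. `"bca"`
#' adjusts the quantile positions by the bias-correction `z0` (from the
#' proportion of bootstrap estimates below the point estimate, ties
#' half-counted) and the acceleration `a_acc` (jackknife skewness).
#'
#' @param x,m,y,covariates data as in [fit_mediation()].
#' @param loss_options list overriding the defaults: `loss`
#'   (`"huber"`, `"ls"`, `"lad"`), `k` (`"auto"` or a number), `grid`,
#'   `min_n_for_selection`, `fallback_k`, `min_prop_inside`,
#'   `k_fixed_in_bootstrap`, `tol`, `max_iter`.
#' @param level confidence level.
#' @param B number of bootstrap resamples (at least 500).
#' @param seed integer seed.
#' @param method `"prct"` or `"bca"`.
#' @param statistic `"product"` or `"difference"`.
#' @param keep_boot keep the bootstrap replicates in the result.
#' @return an `interval_estimate`; elements `point` (full-data
#'   estimate), `redraws` and optionally `boot` are attached.
#' @export
bootstrap_ci <- function(x, m, y, covariates = NULL, loss_options = NULL,
                         level = 0.95, B = 2000L, seed = 1L,
                         method = c("prct", "bca"),
                         statistic = c("product", "difference"),
                         keep_boot = FALSE) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  .check_level(level)
  if (B < 500) stop("'B' must be at least 500", call. = FALSE)
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  .check_xmy(x, m, y)
  opts <- .resolve_loss_options(loss_options)

  full <- .fit_with_options(x, m, y, covariates, opts)
  theta_hat <- if (statistic == "product") full$ab_product else
    full$ab_difference

  k_boot <- .bootstrap_k(opts, full)
  covm <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(x), ncol = 0)
  } else as.matrix(covariates)
  storage.mode(covm) <- "double"

  set.seed(seed)
  res <- cpp_boot_ab(x, m, y, covm, as.integer(B),
                     .loss_codes[[opts$loss]], k_boot, opts$grid,
                     as.integer(opts$min_n_for_selection), opts$fallback_k,
                     opts$min_prop_inside, opts$tol,
                     as.integer(opts$max_iter), statistic == "difference")
  theta_boot <- if (statistic == "product") as.numeric(res$ab) else
    as.numeric(res$cdiff)

  alpha <- 1 - level
  if (method == "prct" || stats::sd(theta_boot) == 0) {
    qs <- quantile(theta_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    qs <- .bca_quantiles(theta_boot, theta_hat, alpha,
                         jack = .jackknife_theta(x, m, y, covariates, opts,
                                                 statistic))
  }
  extra <- list(point = theta_hat, redraws = res$redraws,
                statistic = statistic)
  if (keep_boot) extra$boot <- theta_boot
  new_interval(qs[1], qs[2], level, method, n_resamples = as.integer(B),
               seed = seed, extra = extra)
}

# fixed k to use inside the bootstrap; negative = per-resample selection
.bootstrap_k <- function(opts, full_fit) {
  if (opts$loss != "huber") return(1.345)
  if (!identical(opts$k, "auto")) return(as.numeric(opts$k))
  if (isTRUE(opts$k_fixed_in_bootstrap)) {
    # freeze the full-data selection (outcome-equation k governs b-hat;
    # use the median selected k across the three equations)
    ks <- vapply(full_fit$tuning, function(t) t$k_hat, numeric(1))
    return(median(ks))
  }
  -1
}

.jackknife_theta <- function(x, m, y, covariates, opts, statistic) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    cv <- if (is.null(covariates)) NULL else covariates[-i, , drop = FALSE]
    fit <- .fit_with_options(x[-i], m[-i], y[-i], cv, opts)
    if (statistic == "product") fit$ab_product else fit$ab_difference
  }, numeric(1))
}

# standard BCa construction: adjusted quantile positions from the
# bias-correction z0 and the jackknife acceleration
.bca_quantiles <- function(theta_boot, theta_hat, alpha, jack) {
  B <- length(theta_boot)
  prop <- (sum(theta_boot < theta_hat) +
             0.5 * sum(theta_boot == theta_hat)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a_acc <- if (den == 0) 0 else num / den
  zlo <- qnorm(alpha / 2)
  zhi <- qnorm(1 - alpha / 2)
  a1 <- pnorm(z0 + (z0 + zlo) / (1 - a_acc * (z0 + zlo)))
  a2 <- pnorm(z0 + (z0 + zhi) / (1 - a_acc * (z0 + zhi)))
  quantile(theta_boot, c(a1, a2), names = FALSE)
}

#' Standard errors of the path coefficients
#'
#' Convenience extractor: robust sandwich SEs of `a` (mediator equation)
#' and `b` (outcome equation) from a `mediation_fit`.
#'
#' @param fit a `mediation_fit`.
#' @return named list with `se_a`, `se_b` and the two
#'   `covariance_estimate` objects.
#' @export
mediation_se <- function(fit) {
  stopifnot(inherits(fit, "mediation_fit"))
  va <- robust_vcov(fit$fit_mediator)
  vb <- robust_vcov(fit$fit_outcome)
  list(se_a = sqrt(va$matrix[2L, 2L]), se_b = sqrt(vb$matrix[3L, 3L]),
       vcov_mediator = va, vcov_outcome = vb)
}
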