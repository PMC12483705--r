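#' Simulation design for the simple mediation model
#'
#' Describes one scenario of the simulation harness: path coefficients,
#' sample size, error distribution, replication count and inference
#' settings. Data are generated from the structural direction of the
#' model: \eqn{M = aX + e_2}, \eqn{Y = c'X + bM + e_3}, with intercepts
#' zero, \eqn{X} standard normal by default, and \eqn{e_2, e_3} drawn
#' independently from `error_dist`.
#'
#' Default effect sizes follow the conventional small/medium values of
#' the mediation literature (0.14 and 0.39); the default direct effect
#' is zero.
#'
#' @param a,b,c_prime path coefficients.
#' @param n sample size per replication.
#' @param error_dist an [error_dist()] or one of its names.
#' @param x_dist `function(n)` drawing the independent variable.
#' @param n_reps number of replications.
#' @param level confidence level for rejection studies.
#' @param ci_methods subset of `c("sobel_normal", "monte_carlo", "prct",
#'   "bca")`.
#' @param B bootstrap resamples per replication (bootstrap methods only).
#' @param n_draws Monte-Carlo draws for the product-distribution method.
#' @param seed master seed; all replication-level seeds derive from it.
#' @return list of class `simulation_design`.
#' @export
mediation_design <- function(a = 0.39, b = 0.39, c_prime = 0, n = 200L,
                             error_dist = "normal",
                             x_dist = function(n) rnorm(n),
                             n_reps = 1000L, level = 0.95,
                             ci_methods = c("sobel_normal", "monte_carlo"),
                             B = 1000L, n_draws = 10000L, seed = 1L) {
  if (is.character(error_dist)) error_dist <- error_dist(error_dist)
  stopifnot(inherits(error_dist, "error_dist"), n >= 10, n_reps >= 1)
  .check_level(level)
  methods <- match.arg(ci_methods,
                       c("sobel_normal", "monte_carlo", "prct", "bca"),
                       several.ok = TRUE)
  structure(list(a = a, b = b, c_prime = c_prime, n = as.integer(n),
                 error_dist = error_dist, x_dist = x_dist,
                 n_reps = as.integer(n_reps), level = level,
                 ci_methods = methods, B = as.integer(B),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "simulation_design")
}

# deterministic 32-bit replication seed derived from (seed, rep, stream)
.rep_seed <- function(seed, rep_index, stream = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(rep_index) * 1000003 +
                as.double(stream) * 69621) %% 2147483629) + 1L
}

#' Generate one mediation dataset
#'
#' Draws `(x, m, y)` from the structural model of a
#' [mediation_design()]. Deterministic given `(design$seed, rep_index)`.
#'
#' @param design a `simulation_design`.
#' @param rep_index replication index (enters the derived seed).
#' @return list with numeric vectors `x`, `m`, `y`.
#' @export
gen_mediation_data <- function(design, rep_index = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(.rep_seed(design$seed, rep_index))
  n <- design$n
  x <- design$x_dist(n)
  e2 <- design$error_dist$sampler(n)
  e3 <- design$error_dist$sampler(n)
  m <- design$a * x + e2
  y <- design$c_prime * x + design$b * m + e3
  list(x = x, m = m, y = y)
}

.fit_estimator <- function(dat, estimator, design) {
  switch(estimator,
    ls = fit_mediation(dat$x, dat$m, dat$y, loss = loss_spec("ls")),
    lad = fit_mediation(dat$x, dat$m, dat$y, loss = loss_spec("lad")),
    huber = fit_mediation_auto(dat$x, dat$m, dat$y),
    huber_fixed = fit_mediation(dat$x, dat$m, dat$y,
                                loss = loss_spec("huber", 1.345)),
    stop("unknown estimator: ", estimator, call. = FALSE))
}

#' Mean-squared-error comparison of indirect-effect estimators
#'
#' For each replication the design's data are generated and each
#' requested estimator is fitted; the product estimator
#' \eqn{\hat a \hat b} is recorded. MSE and SD are reported on the plain
#' scale by default; `mse_scale = "n"` multiplies squared deviations by
#' the sample size. Replication-level fit failures are excluded and
#' counted.
#'
#' @param design a [mediation_design()].
#' @param estimators subset of `c("ls", "lad", "huber", "huber_fixed")`;
#'   `"huber"` uses per-equation data-driven tuning.
#' @param mse_scale `"plain"` or `"n"`.
#' @return list of class `simulation_summary` with a `results` data
#'   frame (estimator, mse, sd, bias, n_fail) and `estimates`, the
#'   replication-by-estimator matrix of indirect-effect estimates.
#' @export
run_mse_study <- function(design, estimators = c("ls", "lad", "huber"),
                          mse_scale = c("plain", "n")) {
  stopifnot(inherits(design, "simulation_design"))
  mse_scale <- match.arg(mse_scale)
  estimators <- match.arg(estimators,
                          c("ls", "lad", "huber", "huber_fixed"),
                          several.ok = TRUE)
  ab_true <- design$a * design$b
  est <- matrix(NA_real_, design$n_reps, length(estimators),
                dimnames = list(NULL, estimators))
  for (r in seq_len(design$n_reps)) {
    dat <- gen_mediation_data(design, r)
    for (e in estimators) {
      est[r, e] <- tryCatch(.fit_estimator(dat, e, design)$ab_product,
                            error = function(err) NA_real_)
    }
  }
  scale_factor <- if (mse_scale == "n") design$n else 1
  results <- do.call(rbind, lapply(estimators, function(e) {
    v <- est[, e]
    ok <- v[!is.na(v)]
    data.frame(estimator = e,
               mse = scale_factor * mean((ok - ab_true)^2),
               sd = sqrt(scale_factor) * stats::sd(ok),
               bias = mean(ok) - ab_true,
               n_fail = sum(is.na(v)))
  }))
  structure(list(type = "mse", results = results, estimates = est,
                 ab_true = ab_true, design = design,
                 n_reps_completed = design$n_reps),
            class = "simulation_summary")
}

.ci_for_method <- function(method, fit, dat, design, rep_index, estimator) {
  if (method %in% c("sobel_normal", "monte_carlo")) {
    se <- mediation_se(fit)
    if (method == "sobel_normal") {
      sobel_ci(fit$a, fit$b, se$se_a, se$se_b, level = design$level)
    } else {
      mc_product_ci(fit$a, fit$b, se$se_a, se$se_b, level = design$level,
                    n_draws = design$n_draws,
                    seed = .rep_seed(design$seed, rep_index, 1L))
    }
  } else {
    loss_options <- switch(estimator,
      ls = list(loss = "ls"),
      lad = list(loss = "lad"),
      huber = list(loss = "huber", k = "auto"),
      huber_fixed = list(loss = "huber", k = 1.345))
    bootstrap_ci(dat$x, dat$m, dat$y, loss_options = loss_options,
                 level = design$level, B = design$B,
                 seed = .rep_seed(design$seed, rep_index, 2L),
                 method = method)
  }
}

#' Type-I error / power study
#'
#' For each replication and each requested interval method, records
#' whether the confidence interval for the indirect effect excludes
#' zero. With a design whose true `a * b` is zero the aggregated
#' proportion is the empirical type-I error; otherwise it is power.
#' Binomial standard errors accompany each rate.
#'
#' @inheritParams run_mse_study
#' @return list of class `simulation_summary` with a `results` data
#'   frame (estimator, method, rate, se, n_used) and `mode`
#'   (`"type1"` or `"power"`).
#' @export
run_rejection_study <- function(design, estimators = c("ls", "lad", "huber")) {
  stopifnot(inherits(design, "simulation_design"))
  estimators <- match.arg(estimators,
                          c("ls", "lad", "huber", "huber_fixed"),
                          several.ok = TRUE)
  methods <- design$ci_methods
  reject <- array(NA, dim = c(design$n_reps, length(estimators),
                              length(methods)),
                  dimnames = list(NULL, estimators, methods))
  for (r in seq_len(design$n_reps)) {
    dat <- gen_mediation_data(design, r)
    for (e in estimators) {
      fit <- tryCatch(.fit_estimator(dat, e, design),
                      error = function(err) NULL)
      if (is.null(fit)) next
      for (mth in methods) {
        ci <- tryCatch(.ci_for_method(mth, fit, dat, design, r, e),
                       error = function(err) NULL)
        if (!is.null(ci)) reject[r, e, mth] <- (ci$lower > 0 || ci$upper < 0)
      }
    }
  }
  results <- do.call(rbind, lapply(estimators, function(e) {
    do.call(rbind, lapply(methods, function(mth) {
      v <- reject[, e, mth]
      ok <- v[!is.na(v)]
      rate <- mean(ok)
      data.frame(estimator = e, method = mth, rate = rate,
                 se = sqrt(rate * (1 - rate) / length(ok)),
                 n_used = length(ok))
    }))
  }))
  structure(list(type = "rejection",
                 mode = if (design$a * design$b == 0) "type1" else "power",
                 results = results, design = design,
                 n_reps_completed = design$n_reps),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("<simulation_summary> ", x$type,
      if (!is.null(x$mode)) paste0(" (", x$mode, ")"), "\n", sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}
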