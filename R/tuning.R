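#' Nonparametric estimate of the efficiency factor
#'
#' Estimates \eqn{\tau^2(k)} from regression residuals as
#' \deqn{\hat\tau^2(k) = \frac{n^{-1}\sum_i \psi_k^2(r_i/\hat\sigma)}
#'   {\left[n^{-1}\sum_i \psi_k'(r_i/\hat\sigma)\right]^2},}
#' where \eqn{\psi_k'} is the indicator of \eqn{|u| \le k}. The estimate
#' is undefined (returned as `NA`) when every standardized residual
#' exceeds `k` in magnitude, since the denominator is then 0.
#'
#' @param residuals numeric residual vector, length at least 2.
#' @param k positive tuning constant.
#' @param scale positive residual scale (typically [mad_scale()]).
#' @return nonnegative scalar, or `NA` when undefined.
#' @export
empirical_tau2 <- function(residuals, k, scale) {
  .check_k(k)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("'scale' must be a positive number", call. = FALSE)
  if (length(residuals) < 2L)
    stop("need at least 2 residuals", call. = FALSE)
  as.numeric(cpp_tau2_curve(residuals / scale, k))
}

#' Data-driven selection of the Huber tuning constant
#'
#' Evaluates the nonparametric \eqn{\hat\tau^2(k)} curve over a grid of
#' candidate constants and returns the minimizer; ties are broken toward
#' the largest minimizing `k`. Grid points where the estimate is
#' undefined (no standardized residual within `[-k, k]`) are excluded.
#' When the sample is smaller than `min_n_for_selection`, or fewer than
#' two grid points are defined, selection is judged unreliable and the
#' moderate conventional constant `fallback_k = 1.345` is returned with
#' `fallback_used = TRUE`: with few observations the selected-k Sobel
#' test is anti-conservative, and the fixed constant behaves better.
#'
#' @param residuals numeric residual vector.
#' @param scale positive residual scale.
#' @param grid increasing positive grid of candidate `k`, by default
#'   [default_k_grid()] (step 0.01 up to 3, in standardized units).
#' @param min_n_for_selection minimum sample size for data-driven
#'   selection.
#' @param fallback_k constant used when selection is skipped.
#' @param min_prop_inside minimum fraction of standardized residuals that
#'   must fall inside `[-k, k]` for a grid point to enter the
#'   minimization. Below this the denominator of the nonparametric
#'   estimate rests on a handful of observations and its noise creates
#'   spurious minima at tiny `k`; the default 0.5 also means at most half
#'   of the sample may be treated as outlying, consistent with outliers
#'   being a minority of the data.
#' @return an object of class `tuning_result`: `k_hat`, `tau2_hat`,
#'   `grid`, `tau2_curve`, `fallback_used`, `n`.
#' @export
select_k <- function(residuals, scale, grid = default_k_grid(),
                     min_n_for_selection = 30L, fallback_k = 1.345,
                     min_prop_inside = 0.5) {
  if (length(grid) == 0) stop("'grid' must be nonempty", call. = FALSE)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing and positive", call. = FALSE)
  n <- length(residuals)
  curve <- rep(NA_real_, length(grid))
  fallback <- FALSE
  k_hat <- fallback_k
  tau2_hat <- NA_real_
  stopifnot(min_prop_inside >= 0, min_prop_inside <= 1)
  if (n < min_n_for_selection || scale <= 0) {
    fallback <- TRUE
  } else {
    min_inside <- max(2L, as.integer(ceiling(min_prop_inside * n)))
    curve <- as.numeric(cpp_tau2_curve(residuals / scale, grid, min_inside))
    finite <- which(is.finite(curve))
    if (length(finite) < 2L) {
      fallback <- TRUE
    } else {
      best <- finite[max(which(curve[finite] <= min(curve[finite])))]
      k_hat <- grid[best]
      tau2_hat <- curve[best]
    }
  }
  structure(list(k_hat = k_hat, tau2_hat = tau2_hat, grid = grid,
                 tau2_curve = curve, fallback_used = fallback, n = n),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> k_hat = %g (tau2 = %g, n = %d%s)\n",
              x$k_hat, x$tau2_hat, x$n,
              if (x$fallback_used) ", fallback" else ""))
  invisible(x)
}

#' Mediation fit with per-equation data-driven tuning constants
#'
#' For each of the three mediation equations independently: (1) an
#' initial Huber fit at `k = 1.345`; (2) residuals and MAD scale from
#' that fit; (3) tuning-constant selection by [select_k()]; (4) a refit
#' at the selected constant. By default a single select-then-refit pass
#' is performed; `refine_rounds > 1` alternates selection and refitting.
#' When selection falls back, the equation keeps the initial `k = 1.345`
#' fit.
#'
#' @inheritParams fit_mediation
#' @param k_init initial Huber constant.
#' @param grid candidate grid for selection.
#' @param min_n_for_selection see [select_k()].
#' @param fallback_k see [select_k()].
#' @param min_prop_inside see [select_k()].
#' @param refine_rounds number of select-then-refit passes.
#' @param tol,max_iter IRLS controls, as in [irls_fit()].
#' @return a `mediation_fit` whose `tuning` element is a named list of
#'   three `tuning_result` objects (`total`, `mediator`, `outcome`).
#' @examples
#' set.seed(7)
#' x <- rnorm(400); m <- 0.39 * x + rt(400, df = 3)
#' y <- 0.39 * m + rt(400, df = 3)
#' fit <- fit_mediation_auto(x, m, y)
#' fit$tuning$outcome$k_hat
#' @export
fit_mediation_auto <- function(x, m, y, covariates = NULL, k_init = 1.345,
                               grid = default_k_grid(),
                               min_n_for_selection = 30L,
                               fallback_k = 1.345, min_prop_inside = 0.5,
                               refine_rounds = 1L,
                               tol = 1e-8, max_iter = 200L) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  .check_xmy(x, m, y)
  .check_k(k_init)
  if (length(grid) == 0 || any(grid <= 0) ||
      is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing and positive", call. = FALSE)
  d <- .build_designs(x, m, covariates)

  fit_one <- function(design, resp, eq) {
    res <- tryCatch(
      cpp_fit_eq_auto(design, resp, k_init, grid, min_n_for_selection,
                      fallback_k, min_prop_inside, tol, max_iter,
                      as.integer(refine_rounds), TRUE),
      error = function(e) stop(sprintf("%s equation: %s", eq,
                                       conditionMessage(e)), call. = FALSE))
    f <- res$fit
    fit <- structure(list(
      coefficients = as.numeric(f$coefficients),
      residuals = as.numeric(f$residuals),
      scale = f$scale,
      loss = loss_spec("huber", k = res$k_hat),
      objective = f$objective,
      n_iter = f$n_iter,
      converged = f$converged,
      start_index = f$start_index + 1L,
      n = length(resp),
      design = design,
      response = resp
    ), class = "irls_fit")
    curve <- as.numeric(res$curve)
    if (!length(curve)) curve <- rep(NA_real_, length(grid))
    tuning <- structure(list(k_hat = res$k_hat, tau2_hat = res$tau2_hat,
                             grid = grid, tau2_curve = curve,
                             fallback_used = res$fallback_used,
                             n = length(resp)),
                        class = "tuning_result")
    list(fit = fit, tuning = tuning)
  }

  ft <- fit_one(d$total, y, "total")
  fm <- fit_one(d$mediator, m, "mediator")
  fo <- fit_one(d$outcome, y, "outcome")
  .assemble_mediation_fit(ft$fit, fm$fit, fo$fit,
                          tuning = list(total = ft$tuning,
                                        mediator = fm$tuning,
                                        outcome = fo$tuning))
}
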