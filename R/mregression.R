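#' MAD scale estimate
#'
#' Median absolute deviation about the median, divided by the 0.75
#' quantile of the standard normal (equivalently multiplied by 1.4826...)
#' so that the estimate is consistent for the standard deviation under
#' normal errors. A value of 0 signals a degenerate (dispersion-free)
#' residual vector and is returned as such; callers treat it as an
#' exact-fit signal.
#'
#' @param residuals numeric vector, length at least 2.
#' @return nonnegative scalar.
#' @examples
#' mad_scale(c(1, 2, 3, 4, 5))  # 1.4826
#' @export
mad_scale <- function(residuals) {
  if (!is.numeric(residuals) || length(residuals) < 2L)
    stop("'residuals' must be a numeric vector of length >= 2",
         call. = FALSE)
  if (anyNA(residuals)) stop("'residuals' contains NA", call. = FALSE)
  cpp_mad_scale(residuals)
}

#' Fit one regression equation by IRLS M-estimation
#'
#' Minimizes \eqn{\sum_i \rho(r_i / \hat\sigma)} by iteratively reweighted
#' least squares: at each iteration the residuals are standardized by the
#' MAD scale, weights \eqn{w_i = \psi(r_i/\hat\sigma)/(r_i/\hat\sigma)}
#' are formed, and a weighted least-squares problem is solved. Several
#' starting points are used to guard against multiple local minima; the
#' fit with the smallest objective wins. For the LS loss the solution is
#' the ordinary least-squares fit regardless of starts.
#'
#' When the MAD of the residuals hits 0 at an iterate, either the fit is
#' exact (all residuals 0: the interpolating solution is returned as
#' converged) or the scale falls back to the mean absolute residual times
#' \eqn{\sqrt{\pi/2}}, its normal-consistent counterpart.
#'
#' @param design numeric matrix including the intercept column; must have
#'   full column rank and more rows than columns.
#' @param response numeric response vector.
#' @param loss a [loss_spec()].
#' @param starts optional list of starting coefficient vectors. The
#'   default uses the OLS solution and an LAD approximation reached by a
#'   short LAD-weighted IRLS run from the OLS start.
#' @param tol convergence tolerance on the maximum relative coefficient
#'   change.
#' @param max_iter iteration cap per start.
#' @param scale `"iterated"` re-estimates the MAD scale every iteration
#'   (the default); `"fixed"` freezes the scale at its value from the OLS
#'   residuals.
#' @return an object of class `irls_fit`: list with `coefficients`,
#'   `residuals`, `scale`, `loss`, `objective`, `n_iter`, `converged`,
#'   `start_index`, `n`, `design`, `response`.
#' @export
irls_fit <- function(design, response, loss = loss_spec("huber"),
                     starts = NULL, tol = 1e-8, max_iter = 200L,
                     scale = c("iterated", "fixed")) {
  scale <- match.arg(scale)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  response <- as.numeric(response)
  stopifnot(inherits(loss, "loss_spec"), tol > 0, max_iter >= 1)
  if (nrow(design) != length(response))
    stop("design and response dimensions disagree", call. = FALSE)
  if (nrow(design) <= ncol(design))
    stop("need more observations than coefficients", call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient", call. = FALSE)

  smat <- if (is.null(starts)) {
    matrix(numeric(0), nrow = ncol(design), ncol = 0)
  } else {
    if (!length(starts)) stop("'starts' must be nonempty", call. = FALSE)
    do.call(cbind, lapply(starts, as.numeric))
  }
  fixed_scale <- -1
  if (scale == "fixed") {
    ols <- stats::lm.fit(design, response)
    fixed_scale <- cpp_mad_scale(ols$residuals)
    if (fixed_scale <= 0)
      stop("fixed-scale fit is degenerate: MAD of OLS residuals is 0",
           call. = FALSE)
  }
  k <- if (loss$name == "huber") loss$k else 1
  res <- cpp_irls_fit(design, response, .loss_codes[[loss$name]], k,
                      smat, tol, max_iter, fixed_scale)
  if (res$obj_violations > 0)
    warning(sprintf("IRLS objective increased in %d iteration(s)",
                    res$obj_violations), call. = FALSE)
  structure(list(
    coefficients = as.numeric(res$coefficients),
    residuals = as.numeric(res$residuals),
    scale = res$scale,
    loss = loss,
    objective = res$objective,
    n_iter = res$n_iter,
    converged = res$converged,
    start_index = res$start_index + 1L,
    n = length(response),
    design = design,
    response = response
  ), class = "irls_fit")
}

#' @export
print.irls_fit <- function(x, ...) {
  cat("<irls_fit> loss =", x$loss$name,
      if (x$loss$name == "huber") sprintf("(k = %g)", x$loss$k) else "",
      "\n  coefficients:", signif(x$coefficients, 5),
      "\n  scale:", signif(x$scale, 5),
      " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  invisible(x)
}

.build_designs <- function(x, m, covariates) {
  n <- length(x)
  cov <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    cm
  }
  list(
    total = cbind(intercept = 1, x = x, cov),
    mediator = cbind(intercept = 1, x = x, cov),
    outcome = cbind(intercept = 1, x = x, m = m, cov),
    cov = cov
  )
}

.check_xmy <- function(x, m, y) {
  if (length(x) != length(m) || length(x) != length(y))
    stop("'x', 'm' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 10L)
    stop("need at least 10 observations", call. = FALSE)
  if (anyNA(x) || anyNA(m) || anyNA(y))
    stop("missing values in x, m or y; drop incomplete rows first",
         call. = FALSE)
}

#' Fit the three mediation equations with a common loss
#'
#' Fits the total-effect equation (`y ~ x`, coefficient c), the mediator
#' equation (`m ~ x`, coefficient a) and the outcome equation
#' (`y ~ x + m`, coefficients c' and b) by [irls_fit()], all with the same
#' loss, and forms the two indirect-effect estimators: the product
#' \eqn{\hat a \hat b} and the difference \eqn{\hat c - \hat c'}. The two
#' coincide exactly for the LS loss and in general differ for robust
#' losses. Optional covariates enter all three equations.
#'
#' @param x,m,y numeric vectors: independent variable, mediator, outcome.
#' @param covariates optional numeric matrix of additional controls.
#' @param loss a [loss_spec()] shared by the three equations.
#' @param ... passed to [irls_fit()] (e.g. `tol`, `scale`).
#' @return an object of class `mediation_fit`: the three `irls_fit`
#'   objects (`fit_total`, `fit_mediator`, `fit_outcome`), the path
#'   coefficients `a`, `b`, `c`, `c_prime`, and `ab_product`,
#'   `ab_difference`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); m <- 0.39 * x + rnorm(200)
#' y <- 0.39 * m + rnorm(200)
#' fit <- fit_mediation(x, m, y, loss = loss_spec("huber", 1.345))
#' fit$ab_product
#' @export
fit_mediation <- function(x, m, y, covariates = NULL,
                          loss = loss_spec("huber"), ...) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  .check_xmy(x, m, y)
  d <- .build_designs(x, m, covariates)
  fits <- list()
  for (eq in c("total", "mediator", "outcome")) {
    resp <- switch(eq, total = y, mediator = m, outcome = y)
    fits[[eq]] <- tryCatch(
      irls_fit(d[[eq]], resp, loss = loss, ...),
      error = function(e) stop(sprintf("%s equation: %s", eq,
                                       conditionMessage(e)), call. = FALSE))
  }
  .assemble_mediation_fit(fits$total, fits$mediator, fits$outcome)
}

.assemble_mediation_fit <- function(fit_total, fit_mediator, fit_outcome,
                                    tuning = NULL) {
  a <- fit_mediator$coefficients[2L]
  b <- fit_outcome$coefficients[3L]
  cc <- fit_total$coefficients[2L]
  cp <- fit_outcome$coefficients[2L]
  structure(list(
    fit_total = fit_total,
    fit_mediator = fit_mediator,
    fit_outcome = fit_outcome,
    a = a, b = b, c = cc, c_prime = cp,
    ab_product = a * b,
    ab_difference = cc - cp,
    tuning = tuning
  ), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit>\n",
      sprintf("  a = %.5g  b = %.5g  c = %.5g  c' = %.5g\n",
              x$a, x$b, x$c, x$c_prime),
      sprintf("  indirect effect: product = %.5g, difference = %.5g\n",
              x$ab_product, x$ab_difference))
  if (!is.null(x$tuning)) {
    ks <- vapply(x$tuning, function(t) t$k_hat, numeric(1))
    cat(sprintf("  selected k: total = %.3g, mediator = %.3g, outcome = %.3g\n",
                ks[["total"]], ks[["mediator"]], ks[["outcome"]]))
  }
  invisible(x)
}
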