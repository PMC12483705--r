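#' @useDynLib remed, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm qnorm rnorm rt dt pt pexp rexp integrate
#'   median mad quantile rbinom density var sd runif complete.cases setNames
NULL

.loss_names <- c("huber", "ls", "lad")
.loss_codes <- c(huber = 1L, ls = 0L, lad = 2L)

#' Loss-function specification
#'
#' Bundles a loss function \eqn{\rho} with its influence curve \eqn{\psi}
#' (the first derivative of the loss) and the IRLS weight
#' \eqn{w(u) = \psi(u)/u}. Three losses are supported: the Huber loss with
#' tuning constant `k` (quadratic within `[-k, k]`, linear outside), the
#' least-squares (LS) loss \eqn{u^2/2}, and the least-absolute-deviation
#' (LAD) loss \eqn{|u|}. All three are nonnegative with \eqn{\rho(0) = 0},
#' even, and nondecreasing in \eqn{|u|}.
#'
#' @param name one of `"huber"`, `"ls"`, `"lad"`.
#' @param k positive tuning constant on the standardized-residual scale;
#'   used only by the Huber loss. The conventional value 1.345 gives 95\%
#'   efficiency under normal errors.
#' @return an object of class `loss_spec` with elements `name`, `k`, and
#'   vectorized functions `rho`, `psi`, `weight`.
#' @examples
#' L <- loss_spec("huber", k = 1.345)
#' L$rho(c(0, 1, 3))
#' @export
loss_spec <- function(name = c("huber", "ls", "lad"), k = 1.345) {
  name <- match.arg(name)
  if (name == "huber") {
    if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
      stop("tuning constant 'k' must be a positive number", call. = FALSE)
  } else {
    k <- NA_real_
  }
  spec <- list(
    name = name,
    k = k,
    rho = switch(name,
      huber = function(u) huber_rho(u, k),
      ls = function(u) u^2 / 2,
      lad = function(u) abs(u)),
    psi = switch(name,
      huber = function(u) huber_psi(u, k),
      ls = function(u) u,
      lad = function(u) sign(u)),
    weight = function(u) irls_weight_impl(u, name, k)
  )
  structure(spec, class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec> ", x$name,
      if (x$name == "huber") sprintf(" (k = %g)", x$k) else "", "\n", sep = "")
  invisible(x)
}

#' Huber loss function
#'
#' \eqn{\rho_k(u) = u^2/2} for \eqn{|u| \le k} and
#' \eqn{k|u| - k^2/2} otherwise; continuous and continuously
#' differentiable at the transition \eqn{|u| = k}.
#'
#' @param u numeric vector of standardized residuals.
#' @param k positive tuning constant.
#' @return numeric vector of loss values.
#' @export
huber_rho <- function(u, k) {
  .check_k(k)
  au <- abs(u)
  ifelse(au <= k, u^2 / 2, k * au - k^2 / 2)
}

#' Huber influence curve
#'
#' The derivative \eqn{\psi_k(u) = d\rho_k/du}: the identity clipped to
#' \eqn{[-k, k]}. Odd and bounded by `k`, which is what confers robustness
#' to outlying responses.
#'
#' @inheritParams huber_rho
#' @return numeric vector with entries in `[-k, k]`.
#' @export
huber_psi <- function(u, k) {
  .check_k(k)
  pmin(pmax(u, -k), k)
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("tuning constant 'k' must be a positive number", call. = FALSE)
  invisible(k)
}

# LAD weight 1/|u| is capped so the weighted-LS step stays finite at
# interpolated points.
.lad_weight_cap <- 1e6

irls_weight_impl <- function(u, name, k) {
  switch(name,
    ls = rep(1, length(u)),
    lad = pmin(1 / abs(u), .lad_weight_cap),
    huber = ifelse(abs(u) <= k, 1, k / abs(u)))
}

#' IRLS weight of a loss at a residual
#'
#' The weight \eqn{w(u) = \psi(u)/u} used by iteratively reweighted least
#' squares, with the limit \eqn{\psi'(0)} at \eqn{u = 0}. For the Huber
#' loss this is 1 inside `[-k, k]` and `k/|u|` outside; for LS it is
#' identically 1; for LAD it is `1/|u|`, capped at `1e6` at zero residuals.
#'
#' @param u numeric vector of standardized residuals.
#' @param loss a [loss_spec()].
#' @return numeric vector of nonnegative weights.
#' @export
irls_weight <- function(u, loss) {
  stopifnot(inherits(loss, "loss_spec"))
  irls_weight_impl(u, loss$name, loss$k)
}

#' Error-distribution specification
#'
#' A named symmetric error distribution with density, CDF and sampler, used
#' both to generate simulation errors and to evaluate the analytic
#' efficiency factor \eqn{\tau^2(k)}. All distributions are centred at 0
#' with a unique median at 0, as required for the population identity
#' between the product and difference forms of the indirect effect.
#'
#' @param name one of `"normal"`, `"laplace"`, `"mixed_normal"`,
#'   `"student_t"`.
#' @param sd standard deviation of the normal component (normal only).
#' @param scale scale parameter of the Laplace distribution.
#' @param epsilon contamination fraction of the normal mixture.
#' @param contam_sd standard deviation of the contaminating normal
#'   component; the default mixture is \eqn{0.9\,N(0,1) + 0.1\,N(0,25)}.
#' @param df degrees of freedom of the Student-t distribution.
#' @return an object of class `error_dist` with elements `name`, `params`,
#'   `density`, `cdf`, `sampler` (a `function(n)` drawing from the current
#'   R random stream), `variance` (possibly `Inf`) and `f0`, the density
#'   at 0.
#' @examples
#' ed <- error_dist("mixed_normal")
#' ed$variance  # 0.9 + 0.1 * 25
#' @export
error_dist <- function(name = c("normal", "laplace", "mixed_normal",
                                "student_t"),
                       sd = 1, scale = 1, epsilon = 0.1, contam_sd = 5,
                       df = 3) {
  name <- match.arg(name)
  out <- switch(name,
    normal = list(
      params = list(sd = sd),
      density = function(u) dnorm(u, sd = sd),
      cdf = function(u) pnorm(u, sd = sd),
      sampler = function(n) rnorm(n, sd = sd),
      variance = sd^2,
      f0 = dnorm(0, sd = sd)),
    laplace = list(
      params = list(scale = scale),
      density = function(u) exp(-abs(u) / scale) / (2 * scale),
      cdf = function(u) ifelse(u < 0, 0.5 * exp(u / scale),
                               1 - 0.5 * exp(-u / scale)),
      sampler = function(n) {
        # difference of two iid exponentials has a Laplace law
        rexp(n, rate = 1 / scale) - rexp(n, rate = 1 / scale)
      },
      variance = 2 * scale^2,
      f0 = 1 / (2 * scale)),
    mixed_normal = list(
      params = list(epsilon = epsilon, contam_sd = contam_sd),
      density = function(u) (1 - epsilon) * dnorm(u) +
        epsilon * dnorm(u, sd = contam_sd),
      cdf = function(u) (1 - epsilon) * pnorm(u) +
        epsilon * pnorm(u, sd = contam_sd),
      sampler = function(n) {
        contaminated <- runif(n) < epsilon
        rnorm(n, sd = ifelse(contaminated, contam_sd, 1))
      },
      variance = (1 - epsilon) + epsilon * contam_sd^2,
      f0 = (1 - epsilon) * dnorm(0) + epsilon * dnorm(0, sd = contam_sd)),
    student_t = list(
      params = list(df = df),
      density = function(u) dt(u, df = df),
      cdf = function(u) pt(u, df = df),
      sampler = function(n) rt(n, df = df),
      variance = if (df > 2) df / (df - 2) else Inf,
      f0 = dt(0, df = df))
  )
  out$name <- name
  structure(out, class = "error_dist")
}

#' @export
print.error_dist <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat("<error_dist> ", x$name, " (", p, ")\n", sep = "")
  invisible(x)
}

#' Analytic efficiency factor of the Huber estimator
#'
#' Evaluates \eqn{\tau^2(k) = E[\psi_k^2] / (E[\psi_k'])^2} for a known
#' error distribution, the multiplier of the asymptotic covariance of the
#' Huber M-estimator. Here
#' \eqn{E[\psi_k^2] = \int_{|u| \le k} u^2 dF + k^2 P(|u| > k)} and
#' \eqn{E[\psi_k'] = F(k) - F(-k)}. The inner integral is evaluated by
#' adaptive quadrature on `[-k, k]` (the integrand is smooth there; the
#' kink of \eqn{\psi} at \eqn{\pm k} lies on the boundary).
#'
#' As \eqn{k \to \infty} the factor tends to the error variance (the LS
#' limit) and as \eqn{k \to 0} to \eqn{1/(4 f(0)^2)} (the LAD limit), so
#' small \eqn{\tau^2} at moderate `k` signals that the Huber loss beats
#' both endpoints for that error law.
#'
#' @param dist an [error_dist()].
#' @param k positive tuning constant.
#' @return a list of class `efficiency_factor` with elements `k`, `tau2`,
#'   `e_psi2`, `e_psi_prime` and `dist_name`.
#' @examples
#' analytic_tau2(error_dist("normal"), 1.345)$tau2  # about 1.0527
#' @export
analytic_tau2 <- function(dist, k) {
  stopifnot(inherits(dist, "error_dist"))
  .check_k(k)
  e_psi_prime <- dist$cdf(k) - dist$cdf(-k)
  if (e_psi_prime <= 0)
    stop("degenerate distribution: F(k) - F(-k) = 0, tau^2 undefined",
         call. = FALSE)
  inner <- integrate(function(u) u^2 * dist$density(u), -k, k,
                     abs.tol = 1e-10, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  e_psi2 <- inner + k^2 * (1 - e_psi_prime)
  structure(list(k = k, tau2 = e_psi2 / e_psi_prime^2,
                 e_psi2 = e_psi2, e_psi_prime = e_psi_prime,
                 dist_name = dist$name),
            class = "efficiency_factor")
}

#' Default tuning-constant grid
#'
#' Equally spaced grid `0.01, 0.02, ..., K`. The default ceiling `K = 3`
#' reflects that standardized normal errors fall in `[-3, 3]` with
#' probability 99.73\%, so larger constants change the fit negligibly.
#'
#' @param k_max grid maximum.
#' @param step grid step.
#' @return increasing numeric vector.
#' @export
default_k_grid <- function(k_max = 3, step = 0.01) {
  stopifnot(k_max > 0, step > 0, step <= k_max)
  seq(step, k_max, by = step)
}

#' Optimal tuning constant for a known error distribution
#'
#' Grid search minimizing [analytic_tau2()]. Ties are broken toward the
#' largest `k` among the minimizers, which preserves efficiency near the
#' normal model when the curve is flat.
#'
#' @param dist an [error_dist()].
#' @param k_grid strictly increasing positive grid; defaults to
#'   [default_k_grid()].
#' @return list with `k_star`, `tau2_star`, and the full `tau2_curve`.
#' @export
optimal_k_analytic <- function(dist, k_grid = default_k_grid()) {
  stopifnot(inherits(dist, "error_dist"))
  if (length(k_grid) == 0)
    stop("'k_grid' must be nonempty", call. = FALSE)
  if (any(k_grid <= 0) || is.unsorted(k_grid, strictly = TRUE))
    stop("'k_grid' must be strictly increasing and positive", call. = FALSE)
  curve <- vapply(k_grid, function(k) analytic_tau2(dist, k)$tau2,
                  numeric(1))
  best <- max(which(curve <= min(curve)))
  list(k_star = k_grid[best], tau2_star = curve[best], k_grid = k_grid,
       tau2_curve = curve)
}
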