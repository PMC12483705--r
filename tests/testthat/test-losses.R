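test_that("Huber loss has the two branches, continuity and symmetry", {
  expect_equal(huber_rho(0, 1.345), 0)
  expect_equal(huber_rho(1, 1.345), 0.5)
  expect_equal(huber_rho(3, 1), 2.5)
  expect_equal(huber_rho(-3, 1), 2.5)
  expect_error(huber_rho(1, -1), "positive")
  expect_error(huber_rho(1, 0), "positive")

  set.seed(11)
  for (k in runif(20, 0.01, 5)) {
    # continuity and smoothness across the transition point
    expect_lt(abs(huber_rho(k - 1e-9, k) - huber_rho(k + 1e-9, k)), 1e-8)
    expect_equal(huber_rho(k, k), k^2 / 2)
    u <- runif(1, -3 * k, 3 * k)
    num_deriv <- (huber_rho(u + 1e-6, k) - huber_rho(u - 1e-6, k)) / 2e-6
    expect_equal(num_deriv, huber_psi(u, k), tolerance = 1e-5)
  }
})

test_that("influence curve is odd, clipped and bounded by k", {
  expect_equal(huber_psi(0, 1), 0)
  expect_equal(huber_psi(2, 1), 1)
  expect_equal(huber_psi(-2, 1), -1)
  set.seed(12)
  u <- rnorm(500, sd = 5)
  for (k in c(0.2, 1, 1.345, 3)) {
    expect_true(all(abs(huber_psi(u, k)) <= k))
    expect_equal(huber_psi(-u, k), -huber_psi(u, k))
  }
})

test_that("IRLS weights equal psi(u)/u with the documented limits", {
  hub <- loss_spec("huber", k = 1)
  expect_equal(irls_weight(0.5, hub), 1)
  expect_equal(irls_weight(2, hub), 0.5)
  expect_equal(irls_weight(0, hub), 1)     # limit psi'(0)
  expect_equal(irls_weight(c(-4, 4), hub), c(0.25, 0.25))

  ls <- loss_spec("ls")
  expect_equal(irls_weight(c(-10, 0, 10), ls), c(1, 1, 1))

  lad <- loss_spec("lad")
  expect_equal(irls_weight(2, lad), 0.5)
  expect_equal(irls_weight(0, lad), 1e6)   # capped, not an error
  expect_error(loss_spec("huber", k = -2), "positive")
})

test_that("error distributions are proper, symmetric and centred", {
  for (nm in c("normal", "laplace", "mixed_normal", "student_t")) {
    ed <- error_dist(nm)
    u <- c(0.3, 1.2, 2.5)
    expect_equal(ed$density(u), ed$density(-u))
    expect_equal(ed$cdf(0), 0.5, tolerance = 1e-12)
    expect_equal(ed$cdf(-u), 1 - ed$cdf(u), tolerance = 1e-10)
    expect_lt(ed$cdf(-1e5), 1e-6)
    expect_gt(ed$cdf(1e5), 1 - 1e-6)
    expect_equal(ed$density(0), ed$f0)
  }
  expect_equal(error_dist("mixed_normal")$variance, 0.9 + 0.1 * 25)
  expect_equal(error_dist("laplace")$variance, 2)
  expect_equal(error_dist("student_t", df = 3)$variance, 3)
  expect_identical(error_dist("student_t", df = 2)$variance, Inf)
})

test_that("analytic tau^2 matches the closed-form normal oracle", {
  nd <- error_dist("normal")
  for (k in c(0.3, 0.8, 1.345, 2, 2.8)) {
    expect_equal(analytic_tau2(nd, k)$tau2, tau2_normal_closed(k),
                 tolerance = 1e-7)
  }
  expect_equal(analytic_tau2(nd, 1.345)$tau2, 1.0527, tolerance = 1e-3)
  expect_error(analytic_tau2(nd, -1), "positive")
})

test_that("analytic tau^2 agrees with a Monte-Carlo oracle", {
  set.seed(31)
  for (nm in c("normal", "mixed_normal")) {
    ed <- error_dist(nm)
    e <- ed$sampler(2e5)
    for (k in c(0.8, 1.345)) {
      mc <- tau2_mc_with_se(e, k)
      expect_lt(abs(analytic_tau2(ed, k)$tau2 - mc$est), 3 * mc$se)
    }
  }
})

test_that("grid search finds the tuning constant minimizing tau^2", {
  nd <- error_dist("normal")
  res <- optimal_k_analytic(nd)
  # tau^2 is strictly decreasing in k under the uncontaminated normal,
  # so the optimum sits at the grid maximum
  expect_equal(res$k_star, 3)
  expect_true(all(diff(res$tau2_curve) < 0))

  # the LAD limit 1/(4 f(0)^2) = 1 is approached at O(k), so the grid
  # minimum sits just above it and well below the LS limit of 2
  lap <- optimal_k_analytic(error_dist("laplace"))
  expect_lte(lap$tau2_star, 1.01)
  expect_lt(lap$k_star, 0.5)

  mix <- optimal_k_analytic(error_dist("mixed_normal"))
  expect_lt(mix$k_star, 3)
  expect_lt(mix$tau2_star, mix$tau2_curve[length(mix$tau2_curve)])

  expect_error(optimal_k_analytic(nd, numeric(0)), "nonempty")
  expect_error(optimal_k_analytic(nd, c(2, 1)), "increasing")
})
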