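test_that("sandwich covariance reduces to classical OLS for large k", {
  set.seed(51)
  n <- 100
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- X %*% c(1, 0.5, -0.5) + rnorm(n)
  fit <- irls_fit(X, y, loss = loss_spec("huber", k = 50))
  vc <- robust_vcov(fit)
  expect_true(isSymmetric(vc$matrix, tol = 1e-12))
  expect_true(all(diag(vc$matrix) > 0))
  # with psi the identity, sigma^2 tau^2 = mean(r^2), so the estimate is
  # the classical OLS covariance
  classical <- solve(crossprod(X)) * sum(fit$residuals^2) / (n - 3)
  expect_equal(vc$matrix, classical, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mean sandwich SE tracks the sampling SD of the a-path", {
  reps <- 300
  a_hat <- se_a <- numeric(reps)
  for (r in seq_len(reps)) {
    dat <- make_med_data(500, a = 0.39, b = 0.39, seed = 5100 + r)
    fit <- fit_mediation(dat$x, dat$m, dat$y,
                         loss = loss_spec("huber", 1.345))
    va <- robust_vcov(fit$fit_mediator)
    a_hat[r] <- fit$a
    se_a[r] <- sqrt(va$matrix[2, 2])
  }
  expect_lt(abs(mean(se_a) / sd(a_hat) - 1), 0.10)
})

test_that("Sobel statistic follows the delta-method arithmetic", {
  st <- sobel_statistic(0, 1, 0.1, 0.2)
  expect_equal(st$se_ab, 0.1)
  expect_equal(st$z, 0)
  st <- sobel_statistic(0.39, 0.39, 0.1, 0.1)
  expect_equal(st$se_ab, 0.39 * 0.1 * sqrt(2), tolerance = 1e-10)
  expect_equal(st$z, 0.39^2 / (0.39 * 0.1 * sqrt(2)), tolerance = 1e-10)
  # swapping the two paths leaves z unchanged
  st2 <- sobel_statistic(0.2, 0.7, 0.05, 0.03)
  st3 <- sobel_statistic(0.7, 0.2, 0.03, 0.05)
  expect_equal(st2$z, st3$z)
  # second-order variant adds se_a^2 se_b^2
  s2 <- sobel_statistic(0.39, 0.39, 0.1, 0.1, variant = "second")
  expect_equal(s2$se_ab^2 - st$se_ab^2, 0.1^2 * 0.1^2, tolerance = 1e-12)
  expect_error(sobel_statistic(1, 1, 0, 0), "degenerate")
})

test_that("Sobel interval matches normal-quantile arithmetic", {
  ci <- sobel_ci(0.39, 0.39, 0.1, 0.1, level = 0.95)
  expect_equal(ci$lower, 0.0440, tolerance = 1e-3)
  expect_equal(ci$upper, 0.2602, tolerance = 1e-3)
  ci0 <- sobel_ci(0, 0.5, 0.1, 0.1)
  expect_equal(ci0$lower, -ci0$upper)
  expect_error(sobel_ci(1, 1, 0.1, 0.1, level = 1), "level")
  expect_error(sobel_ci(1, 1, 0.1, 0.1, level = 0), "level")
})

test_that("Monte-Carlo product interval behaves at the edges", {
  ci <- mc_product_ci(0.3, 0.5, 0, 0, seed = 52)
  expect_equal(ci$lower, 0.15)
  expect_equal(ci$upper, 0.15)
  ci0 <- mc_product_ci(0, 0, 1, 1, n_draws = 2e5, seed = 53)
  expect_lt(ci0$lower, 0)
  expect_gt(ci0$upper, 0)
  expect_equal(ci0$lower, -ci0$upper, tolerance = 0.05)
  # reproducible given the seed
  again <- mc_product_ci(0, 0, 1, 1, n_draws = 2e5, seed = 53)
  expect_identical(c(ci0$lower, ci0$upper), c(again$lower, again$upper))
  expect_warning(mc_product_ci(0.3, 0.3, 0.1, 0.1, n_draws = 500, seed = 1),
                 "1000")
})

test_that("irreparably degenerate designs abort instead of looping", {
  # constant x: every resample is rank deficient, so the redraw cap trips
  x <- rep(1, 30)
  set.seed(54)
  m <- rnorm(30)
  y <- rnorm(30)
  expect_error(suppressWarnings(
    bootstrap_ci(x, m, y, B = 500, seed = 54)))
})

test_that("bootstrap intervals cover the point estimate and reproduce", {
  dat <- make_med_data(150, a = 0.39, b = 0.39, error = "student_t",
                       seed = 55)
  ci <- bootstrap_ci(dat$x, dat$m, dat$y, B = 500, seed = 56)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  again <- bootstrap_ci(dat$x, dat$m, dat$y, B = 500, seed = 56)
  expect_identical(c(ci$lower, ci$upper), c(again$lower, again$upper))
  expect_error(bootstrap_ci(dat$x, dat$m, dat$y, B = 100, seed = 1),
               "at least 500")
})

test_that("BCa agrees with the percentile interval when unskewed", {
  dat <- make_med_data(200, a = 0.39, b = 0.39, seed = 57)
  prct <- bootstrap_ci(dat$x, dat$m, dat$y, B = 1000, seed = 58,
                       method = "prct", keep_boot = TRUE)
  bca <- bootstrap_ci(dat$x, dat$m, dat$y, B = 1000, seed = 58,
                      method = "bca")
  # same bootstrap draws; the adjustment should move endpoints by little
  # when bias-correction and acceleration are near zero
  width <- prct$upper - prct$lower
  expect_lt(abs(bca$lower - prct$lower), 0.25 * width)
  expect_lt(abs(bca$upper - prct$upper), 0.25 * width)
})

test_that("difference-statistic bootstrap targets c - c_prime", {
  dat <- make_med_data(150, a = 0.39, b = 0.39, seed = 59)
  ci <- bootstrap_ci(dat$x, dat$m, dat$y, B = 500, seed = 60,
                     statistic = "difference",
                     loss_options = list(loss = "ls"))
  fit <- fit_mediation(dat$x, dat$m, dat$y, loss = loss_spec("ls"))
  expect_equal(ci$point, fit$ab_difference)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
})
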