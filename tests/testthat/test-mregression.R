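test_that("MAD scale is normal-consistent and flags degenerate vectors", {
  expect_equal(mad_scale(c(1, 2, 3, 4, 5)), 1.4826, tolerance = 1e-3)
  expect_equal(mad_scale(c(-1, 1)), 1.4826, tolerance = 1e-3)
  expect_equal(mad_scale(c(5, 5, 5, 5)), 0)
  v <- c(0.3, -1.2, 0.8, 2.1, -0.4, 0.9, -1.7, 0.2, 1.1, -0.6)
  expect_equal(mad_scale(v + 100), mad_scale(v))  # location invariance
  expect_error(mad_scale(1), "length")
  expect_error(mad_scale(c(1, NA)), "NA")
  set.seed(21)
  e <- rnorm(2e5)
  expect_equal(mad_scale(e), 1, tolerance = 0.01)
})

test_that("exact linear data yields the interpolating fit for any loss", {
  x <- seq(-3, 3, length.out = 25)
  y <- 2 * x + 1
  X <- cbind(1, x)
  for (loss in list(loss_spec("huber", 0.5), loss_spec("ls"),
                    loss_spec("lad"))) {
    fit <- irls_fit(X, y, loss = loss)
    expect_equal(fit$coefficients, c(1, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(abs(fit$residuals) < 1e-9))
    expect_true(fit$converged)
  }
})

test_that("Huber with a large k reproduces OLS; residual identity holds", {
  set.seed(22)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- X %*% c(1, 2, -1) + rnorm(n)
  ols <- lm.fit(X, y)$coefficients
  fit <- irls_fit(X, y, loss = loss_spec("huber", k = 50))
  expect_equal(fit$coefficients, ols, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$residuals, as.numeric(y - X %*% fit$coefficients),
               tolerance = 1e-12)
  # LS loss ignores the starting points entirely
  fit_ls <- irls_fit(X, y, loss = loss_spec("ls"),
                     starts = list(c(100, -50, 7)))
  expect_equal(fit_ls$coefficients, ols, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Huber down-weights a gross response outlier", {
  set.seed(23)
  n <- 50
  x <- seq(-2, 2, length.out = n)
  y <- x + rnorm(n, sd = 0.1)
  x[1] <- 0; y[1] <- 100
  X <- cbind(1, x)
  huber <- irls_fit(X, y, loss = loss_spec("huber", 1.345))
  ols <- lm.fit(X, y)$coefficients
  expect_lt(abs(huber$coefficients[2] - 1), abs(ols[2] - 1))
  expect_lt(abs(huber$coefficients[2] - 1), 0.05)
  # cross-check against an independent Huber implementation (MASS::rlm
  # uses the same loss with an MAD scale; small differences come from its
  # scale update)
  rlm_fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                       scale.est = "MAD", maxit = 100)
  expect_equal(huber$coefficients, unname(coef(rlm_fit)), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("fit is equivariant to response scaling and shifting", {
  set.seed(24)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- X %*% c(0.5, 1.5) + rt(n, df = 3)
  base <- irls_fit(X, y, loss = loss_spec("huber", 1.345))
  scaled <- irls_fit(X, 7 * y, loss = loss_spec("huber", 1.345))
  expect_equal(scaled$coefficients, 7 * base$coefficients, tolerance = 1e-8)
  shifted <- irls_fit(X, y + 3, loss = loss_spec("huber", 1.345))
  expect_equal(shifted$coefficients, base$coefficients + c(3, 0),
               tolerance = 1e-8)
})

test_that("invalid designs and inputs are rejected with clear errors", {
  X <- cbind(1, 1:20, 2 * (1:20))  # collinear
  expect_error(irls_fit(X, rnorm(20)), "rank deficient")
  expect_error(irls_fit(cbind(1, 1:5), rnorm(4)), "disagree")
  expect_error(irls_fit(cbind(1, 1:3, (1:3)^2), rnorm(3)),
               "more observations")
  expect_error(irls_fit(cbind(1, 1:20), rnorm(20), starts = list()),
               "nonempty")
})

test_that("three-equation fit populates both indirect-effect estimators", {
  dat <- make_med_data(5000, a = 0.39, b = 0.39, seed = 31)
  fit <- fit_mediation(dat$x, dat$m, dat$y, loss = loss_spec("huber", 1.345))
  expect_identical(fit$ab_product, fit$a * fit$b)
  expect_identical(fit$ab_difference, fit$c - fit$c_prime)
  se <- mediation_se(fit)
  expect_lt(abs(fit$a - 0.39), 3 * se$se_a)
  expect_lt(abs(fit$b - 0.39), 3 * se$se_b)

  # zero a-path implies zero indirect effect
  dat0 <- make_med_data(5000, a = 0, b = 0.39, seed = 32)
  fit0 <- fit_mediation(dat0$x, dat0$m, dat0$y)
  se0 <- mediation_se(fit0)
  expect_lt(abs(fit0$ab_product), 3 * abs(fit0$b) * se0$se_a + 1e-3)
})

test_that("LS product and difference estimators coincide", {
  dat <- make_med_data(300, error = "student_t", seed = 33)
  fit <- fit_mediation(dat$x, dat$m, dat$y, loss = loss_spec("ls"))
  expect_equal(fit$ab_product, fit$ab_difference, tolerance = 1e-10)
})

test_that("covariates enter all three equations", {
  set.seed(34)
  n <- 300
  z <- rnorm(n)
  x <- rnorm(n) + 0.5 * z
  m <- 0.4 * x + 0.8 * z + rnorm(n)
  y <- 0.4 * m + 0.8 * z + rnorm(n)
  fit <- fit_mediation(x, m, y, covariates = cbind(z = z))
  expect_length(fit$fit_mediator$coefficients, 3)
  expect_length(fit$fit_outcome$coefficients, 4)
  expect_lt(abs(fit$a - 0.4), 0.15)
  expect_lt(abs(fit$b - 0.4), 0.15)
})

test_that("fixed-scale option freezes the scale at the OLS value", {
  set.seed(35)
  X <- cbind(1, rnorm(100))
  y <- X %*% c(1, 2) + rt(100, 3)
  it <- irls_fit(X, y, loss = loss_spec("huber", 1.345), scale = "iterated")
  fx <- irls_fit(X, y, loss = loss_spec("huber", 1.345), scale = "fixed")
  expect_equal(fx$scale, mad_scale(lm.fit(X, y)$residuals))
  expect_equal(it$coefficients, fx$coefficients, tolerance = 0.05)
})
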