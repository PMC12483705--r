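# Closed-form tau^2(k) for standard normal errors, from normal moments:
# E[psi^2] = (2*Phi(k)-1) - 2*k*phi(k) + 2*k^2*(1-Phi(k)),
# E[psi']  = 2*Phi(k)-1.
tau2_normal_closed <- function(k) {
  ep2 <- (2 * pnorm(k) - 1) - 2 * k * dnorm(k) + 2 * k^2 * (1 - pnorm(k))
  epp <- 2 * pnorm(k) - 1
  ep2 / epp^2
}

# Monte-Carlo tau^2 with a block standard error: the sample is split into
# blocks, tau^2 is computed per block, and the SE of the full-sample value
# is sd(blocks)/sqrt(n_blocks).
tau2_mc_with_se <- function(errors, k, n_blocks = 100) {
  psi <- pmin(pmax(errors, -k), k)
  est <- mean(psi^2) / mean(abs(errors) <= k)^2
  blocks <- split(errors, rep(seq_len(n_blocks), length.out = length(errors)))
  per_block <- vapply(blocks, function(e) {
    p <- pmin(pmax(e, -k), k)
    mean(p^2) / mean(abs(e) <= k)^2
  }, numeric(1))
  list(est = est, se = stats::sd(per_block) / sqrt(n_blocks))
}

# Huber objective sum(rho(r / s)) for a fixed scale
huber_objective <- function(beta, X, y, k, s) {
  u <- (y - X %*% beta) / s
  sum(huber_rho(u, k))
}

# small simulated mediation dataset
make_med_data <- function(n, a = 0.39, b = 0.39, c_prime = 0,
                          error = "normal", seed = 1) {
  d <- mediation_design(a = a, b = b, c_prime = c_prime, n = n,
                        error_dist = error, seed = seed)
  gen_mediation_data(d, 1L)
}
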