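# Shared fixtures for the suite. All stochastic tests draw through
# rng_stream() so they are exactly reproducible; the base seed is fixed once
# for the whole suite.
BASE_SEED <- 42L

ovd_zero <- function(mu = 1, beta = 1)
  overdamped_model(fixture_potential("zero"), mu = mu, beta = beta)

ovd_harmonic <- function(k = 1, mu = 1, beta = 1)
  overdamped_model(fixture_potential("harmonic", k = k), mu = mu, beta = beta)

und_zero <- function(m = 1, tau = 1, beta = 1)
  underdamped_model(fixture_potential("zero"), m = m, tau = tau, beta = beta)

# eta-regularized linear phase-space system as a general value problem:
# dq = p/m dt + eta sqrt(2 tau/(m beta)) dw1, dp = -p/tau dt + sqrt(2m/(tau beta)) dw2.
linear_system_problem <- function(eta, m = 1, tau = 1, beta = 1,
                                  terminal = function(X) X[, 2],
                                  running_cost = NULL) {
  value_problem(
    drift = function(t, X) cbind(X[, 2] / m, -X[, 2] / tau),
    volatility = matrix(c(eta * sqrt(2 * tau / (m * beta)), 0,
                          0, sqrt(2 * m / (tau * beta))), 2, 2),
    terminal = terminal,
    running_cost = running_cost,
    drift_jacobian = matrix(c(0, 0, 1 / m, -1 / tau), 2, 2),
    dim = 2L)
}

# |a - b| within 3 combined Monte Carlo standard errors (plus optional
# absolute discretization slack).
expect_within_3se <- function(est, ref, se, slack = 0) {
  expect_lt(abs(est - ref), 3 * se + slack + 1e-12)
}
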