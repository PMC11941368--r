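test_that("Dynkin estimates are exact for deterministic costs", {
  g <- time_grid(0, 1, n = 10)
  p1 <- value_problem(drift = function(t, X) 0 * X, volatility = 1,
                      terminal = function(X) rep(4.2, nrow(X)))
  v <- dynkin_value(0.3, 0, p1, g, M = 50, rng = rng_stream(BASE_SEED))
  expect_equal(v$estimate, 4.2)
  expect_equal(v$se, 0)
  # running cost 1, terminal 0: left-endpoint quadrature gives tf - t exactly
  p2 <- value_problem(drift = function(t, X) 0 * X, volatility = 1,
                      terminal = function(X) rep(0, nrow(X)),
                      running_cost = function(t, X) rep(1, nrow(X)))
  v2 <- dynkin_value(0, 0, p2, g, M = 50, rng = rng_stream(BASE_SEED))
  expect_equal(v2$estimate, 1)
  expect_equal(v2$se, 0)
  # at the terminal time, the value is the terminal cost
  v3 <- dynkin_value(0.3, 1, p1, g, M = 50, rng = rng_stream(BASE_SEED))
  expect_equal(v3$estimate, 4.2)
})

test_that("Dynkin reproduces the linear-system value", {
  g <- time_grid(0, 1, dt = 5e-3)
  prob <- linear_system_problem(eta = 0.1)
  v <- dynkin_value(c(0.4, 1), 0, prob, g, M = 4e3,
                    rng = rng_stream(BASE_SEED))
  expect_within_3se(v$estimate, exp(-1), v$se, slack = 3e-3)
})

test_that("the tangent cocycle has the closed constant-Hessian form", {
  m <- ovd_harmonic(k = 1.7, mu = 0.8)
  g <- time_grid(0, 0.5, n = 25)
  b <- simulate_overdamped_forward(0.2, g, m, 6, rng_stream(BASE_SEED))
  co <- tangent_cocycle_overdamped(b, m)
  expect_equal(co[, 1], rep(1, 6))
  # constant Hessian k: factor at node n is exp(-mu k (t_n - t_0)) exactly
  # (the accumulated-exponent construction sums k dt exactly)
  expect_equal(co[3, 26], exp(-0.8 * 1.7 * 0.5), tolerance = 1e-12)
  # free diffusion: identically one
  b0 <- simulate_overdamped_forward(0.2, g, ovd_zero(), 4,
                                    rng_stream(BASE_SEED))
  expect_true(all(tangent_cocycle_overdamped(b0, ovd_zero()) == 1))
  # cocycle composition: factor(0 -> n) = factor(0 -> k) * factor(k -> n)
  rat <- co[, 26] / co[, 13]
  acc <- exp(-0.8 * 1.7 * sum(g$dt[13:25]))
  expect_equal(rat, rep(acc, 6), tolerance = 1e-10)
})

test_that("d > 1 cocycle products track the matrix exponential", {
  H <- matrix(c(1, 0.3, 0.3, 0.5), 2, 2)  # constant commuting Hessian
  pot <- potential(
    gradient = function(t, Q) Q %*% H,
    hessian = function(t, Q) array(rep(as.numeric(H), each = nrow(Q)),
                                   dim = c(nrow(Q), 2, 2)),
    d = 2L)
  m <- overdamped_model(pot)
  g <- time_grid(0, 0.5, n = 250)
  b <- simulate_overdamped_forward(c(0.1, -0.2), g, m, 3,
                                   rng_stream(BASE_SEED))
  co <- tangent_cocycle_overdamped(b, m)
  ref <- as.matrix(Matrix::expm(-H * 0.5))
  expect_equal(matrix(co[2, 251, , ], 2, 2), ref, tolerance = 5e-3)
})

test_that("BEL overdamped matches the constant-Hessian closed form", {
  g <- time_grid(0, 0.5, dt = 2.5e-3)
  gr <- bel_gradient_overdamped(0.3, 0, ovd_harmonic(), g, function(q) q,
                                running_cost = "none", M = 5e3,
                                rng = rng_stream(BASE_SEED))
  expect_within_3se(gr$estimate, exp(-0.5), gr$se, slack = 3e-3)
  # constant terminal cost: zero gradient within noise
  gr0 <- bel_gradient_overdamped(0.3, 0, ovd_harmonic(), g,
                                 function(q) rep(5, length(q)),
                                 running_cost = "none", M = 3e3,
                                 rng = rng_stream(BASE_SEED))
  expect_within_3se(gr0$estimate, 0, gr0$se)
  expect_error(bel_gradient_overdamped(0.3, 0.5, ovd_harmonic(), g,
                                       function(q) q), "strictly before")
})

test_that("the general estimator specializes to the overdamped one", {
  g <- time_grid(0, 0.5, n = 100)
  term <- function(q) q
  # free diffusion: the two cocycle discretizations coincide exactly
  m0 <- ovd_zero()
  a <- bel_gradient_overdamped(0.2, 0, m0, g, term, "none", M = 500,
                               rng = rng_stream(BASE_SEED))
  p0 <- overdamped_problem(m0, term, "none")
  b <- bel_gradient_general(0.2, 0, p0, g, M = 500,
                            rng = rng_stream(BASE_SEED))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  # harmonic potential: exponential-of-sum vs Euler-product cocycles differ
  # at O(dt); with shared seeds the estimates agree to that order
  mh <- ovd_harmonic()
  ah <- bel_gradient_overdamped(0.2, 0, mh, g, term, "none", M = 2e3,
                                rng = rng_stream(BASE_SEED))
  ph <- overdamped_problem(mh, term, "none")
  bh <- bel_gradient_general(0.2, 0, ph, g, M = 2e3,
                             rng = rng_stream(BASE_SEED))
  expect_equal(ah$estimate, bh$estimate, tolerance = 5e-3)
})

test_that("BEL general recovers the linear-system momentum gradient", {
  g <- time_grid(0, 1, dt = 5e-3)
  prob <- linear_system_problem(eta = 0.1)
  gr <- bel_gradient_general(c(0.2, 1), 0, prob, g, M = 5e3,
                             rng = rng_stream(BASE_SEED), direction = 2L)
  expect_within_3se(gr$estimate, linear_value_gradient(0, 1), gr$se,
                    slack = 5e-3)
})

test_that("adding a constant to the terminal cost shifts values, not gradients", {
  g <- time_grid(0, 0.4, n = 80)
  m <- overdamped_model(fixture_potential("double_well"))
  prob1 <- overdamped_problem(m, function(q) sin(q), "bridge")
  prob2 <- overdamped_problem(m, function(q) sin(q) + 7, "bridge")
  eps <- noise_array(rng_stream(BASE_SEED), 2e3, 80, 1)
  v1 <- dynkin_value(0.1, 0, prob1, g, M = 2e3, noises = eps)
  v2 <- dynkin_value(0.1, 0, prob2, g, M = 2e3, noises = eps)
  expect_equal(v2$estimate - v1$estimate, 7, tolerance = 1e-10)
  g1 <- bel_gradient_overdamped(0.1, 0, m, g, function(q) sin(q),
                                "bridge", M = 2e3, noises = eps)
  g2 <- bel_gradient_overdamped(0.1, 0, m, g, function(q) sin(q) + 7,
                                "bridge", M = 2e3, noises = eps)
  # the shift only adds a mean-zero Ito integral; with shared noise the
  # difference is 7 * mean(I)/T, bounded by its own standard error
  expect_within_3se(g2$estimate - g1$estimate, 0, 3 * (g1$se + g2$se))
})

test_that("estimator variance scales as 1/M", {
  g <- time_grid(0, 0.5, n = 50)
  est_at <- function(M, s) {
    bel_gradient_overdamped(0.3, 0, ovd_harmonic(), g, function(q) q,
                            "none", M = M, rng = rng_stream(s))$estimate
  }
  v_small <- var(vapply(1:12, function(s) est_at(100, s), 0))
  v_big <- var(vapply(1:12, function(s) est_at(900, s), 0))
  slope <- log(v_big / v_small) / log(900 / 100)
  expect_lt(abs(slope + 1), 0.8)
})

test_that("the CRN finite-difference oracle is exact on linear problems", {
  g <- time_grid(0, 0.5, n = 50)
  prob <- value_problem(drift = function(t, X) 0 * X, volatility = 1,
                        terminal = function(X) 3 * X[, 1])
  fd <- fd_gradient_dynkin(0.2, 0, prob, g, M = 200,
                           rng = rng_stream(BASE_SEED))
  expect_equal(fd$estimate, 3, tolerance = 1e-10)
  expect_equal(fd$se, 0, tolerance = 1e-10)
})

test_that("BEL gradients agree with finite differences of the value", {
  # the module's master oracle, here on the double-well fixture with the
  # bridge running cost (the full sweep over fixtures runs in acceptance)
  m <- overdamped_model(fixture_potential("double_well"))
  g <- time_grid(0, 0.3, n = 60)
  term <- function(q) exp(-q^2 / 2)
  prob <- overdamped_problem(m, term, "bridge")
  fd <- fd_gradient_dynkin(0.4, 0, prob, g, step = 1e-2, M = 1e4,
                           rng = rng_stream(BASE_SEED))
  gr <- bel_gradient_overdamped(0.4, 0, m, g, term, "bridge", M = 1e4,
                                rng = rng_stream(BASE_SEED + 1))
  tol <- 3 * sqrt(fd$se^2 + gr$se^2) + 0.02
  expect_lt(abs(fd$estimate - gr$estimate), tol)
})
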