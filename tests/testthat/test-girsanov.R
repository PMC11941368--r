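test_that("free diffusion gives exactly zero log-weights (both dynamics)", {
  g <- time_grid(0, 0.2, n = 20)
  bo <- simulate_overdamped_backward(0.5, g, ovd_zero(), 50,
                                     rng_stream(BASE_SEED))
  expect_true(all(log_weight_overdamped(bo, ovd_zero()) == 0))
  # underdamped: all-zero momenta give zero weight even with a potential
  mu <- underdamped_model(fixture_potential("harmonic"))
  bu <- simulate_underdamped_backward(c(0.5, 0), g, mu, 10, noises = "zero")
  bu$states[, , 2] <- 0
  expect_true(all(log_weight_underdamped(bu, mu) == 0))
})

test_that("one-step weights match direct substitution into the exponent", {
  # constant-gradient potential dU = c over a single backward step
  cc <- 0.8
  pot <- potential(gradient = function(t, q) rep(cc, length(q)),
                   hessian = function(t, q) rep(0, length(q)))
  m <- overdamped_model(pot, mu = 1.3, beta = 0.7)
  g <- time_grid(0, 0.05, n = 1)
  b <- simulate_overdamped_backward(0.4, g, m, 7, rng_stream(BASE_SEED))
  eps <- b$noises[, 1, 1]
  dt <- 0.05
  by_hand <- -(m$beta * m$mu / 4) * dt * cc^2 -
    sqrt(m$beta * m$mu * dt / 2) * cc * eps
  expect_equal(as.numeric(log_weight_overdamped(b, m)), by_hand,
               tolerance = 1e-12)
  # underdamped one step
  mu <- underdamped_model(fixture_potential("harmonic"), m = 2, tau = 0.5,
                          beta = 3)
  bu <- simulate_underdamped_backward(c(0.3, 1.1), g, mu, 7,
                                      rng_stream(BASE_SEED))
  p_pre <- bu$states[, 1, 2]
  cb <- mu$tau * mu$beta / mu$m
  by_hand_u <- -(cb / 4) * dt * p_pre^2 -
    sqrt(cb * dt / 2) * p_pre * bu$noises[, 1, 1]
  expect_equal(as.numeric(log_weight_underdamped(bu, mu)), by_hand_u,
               tolerance = 1e-12)
})

test_that("multi-step weights agree with a literal two-integral transcription", {
  m <- ovd_harmonic(k = 1.4, mu = 0.9, beta = 1.2)
  g <- time_grid(0, 0.1, n = 10)
  b <- simulate_overdamped_backward(0.7, g, m, 11, rng_stream(BASE_SEED))
  lw <- rowSums(log_weight_overdamped(b, m))
  # brute force: accumulate the Riemann sum and the Ito sum separately,
  # path by path, straight from the exponent's two integrals
  brute <- numeric(11)
  for (i in 1:11) {
    riemann <- 0; ito <- 0
    for (n in 1:10) {
      grad <- 1.4 * b$states[i, n, 1]
      riemann <- riemann + g$dt[n] * grad^2
      ito <- ito + sqrt(g$dt[n]) * grad * b$noises[i, n, 1]
    }
    brute[i] <- -(m$beta * m$mu / 4) * riemann -
      sqrt(m$beta * m$mu / 2) * ito
  }
  expect_equal(lw, brute, tolerance = 1e-12)
})

test_that("backward-adapted weights are a normalized change of measure", {
  # the anchor-side (backward-predictable) discretization is an exact
  # discrete martingale: E[exp(-g)] = 1
  m <- overdamped_model(fixture_potential("double_well"))
  g <- time_grid(0, 0.1, n = 100)
  M <- 2e4
  b <- simulate_overdamped_backward(0.5, g, m, M, rng_stream(BASE_SEED))
  w <- exp(rowSums(log_weight_overdamped(b, m, at = "anchor")))
  expect_within_3se(mean(w), 1, sd(w) / sqrt(M))
  # underdamped, harmonic
  mu <- underdamped_model(fixture_potential("harmonic"))
  bu <- simulate_underdamped_backward(c(0.2, 0.4), g, mu, M,
                                      rng_stream(BASE_SEED + 1))
  wu <- exp(rowSums(log_weight_underdamped(bu, mu, at = "anchor")))
  expect_within_3se(mean(wu), 1, sd(wu) / sqrt(M))
})

test_that("generated-node weights carry the phase-space contraction factor", {
  # the pre-point (density) discretization couples each state to its own
  # draw; for U = 0 its exponential averages to exp(T d / tau) exactly in
  # the limit - the factor the continuum pre-point identity absorbs
  mu <- und_zero()
  g <- time_grid(0, 0.1, n = 100)
  M <- 2e4
  bu <- simulate_underdamped_backward(c(0, 0.3), g, mu, M,
                                      rng_stream(BASE_SEED))
  wu <- exp(rowSums(log_weight_underdamped(bu, mu)))
  expect_within_3se(mean(wu), exp(0.1), sd(wu) / sqrt(M), slack = 2e-3)
})

test_that("the solver returns the initial density exactly at the start time", {
  g <- time_grid(0, 0.1, n = 10)
  est <- fp_density_overdamped(c(-1, 0, 2), 0, ovd_harmonic(), g,
                               function(q) dnorm(q, log = TRUE), M = 10,
                               rng = rng_stream(BASE_SEED))
  expect_equal(est$mean, dnorm(c(-1, 0, 2)))
  expect_equal(est$se, rep(0, 3))
})

test_that("free-diffusion density matches the heat-kernel convolution", {
  g <- time_grid(0, 0.4, dt = 2e-3)
  est <- fp_density_overdamped(c(-1, 0, 1), 0.4, ovd_zero(), g,
                               function(q) dnorm(q, log = TRUE), M = 4e3,
                               rng = rng_stream(BASE_SEED))
  ref <- dnorm(c(-1, 0, 1), sd = sqrt(1 + 2 * 0.4))
  for (i in 1:3) expect_within_3se(est$mean[i], ref[i], est$se[i])
})

test_that("quadratic-potential density matches the OU closed form", {
  g <- time_grid(0, 0.5, dt = 1e-3)
  s0 <- 0.6
  est <- fp_density_overdamped(c(-0.5, 0.2, 1), 0.5, ovd_harmonic(), g,
                               function(q) dnorm(q, sd = s0, log = TRUE),
                               M = 4e3, rng = rng_stream(BASE_SEED))
  # exact OU marginal from a Gaussian start
  v <- s0^2 * exp(-2 * 0.5) + (1 - exp(-2 * 0.5))
  ref <- dnorm(c(-0.5, 0.2, 1), sd = sqrt(v))
  for (i in 1:3) expect_within_3se(est$mean[i], ref[i], est$se[i],
                                   slack = 2e-3)
})

test_that("phase-space density matches the linear-system Gaussian law", {
  g <- time_grid(0, 0.4, dt = 2e-3)
  law0 <- gaussian_law(c(0, 0), diag(c(0.49, 0.64)))
  lawT <- linear_underdamped_pushforward(law0, 0.4)
  pts <- data.frame(q = c(-0.5, 0, 0.8), p = c(0.3, 0, -0.4))
  est <- fp_density_underdamped(pts, 0.4, und_zero(), g,
    function(q, p) dnorm(q, sd = 0.7, log = TRUE) +
      dnorm(p, sd = 0.8, log = TRUE),
    M = 4e3, rng = rng_stream(BASE_SEED))
  ref <- gaussian_density(lawT, as.matrix(pts))
  for (i in 1:3) expect_within_3se(est$mean[i], ref[i], est$se[i],
                                   slack = 2e-3)
})

test_that("estimated densities conserve probability mass", {
  # scaled-down phase-space run: static double-well drift from a quartic
  # well. The quadrature grid must resolve the thermal width and the step
  # must be fine enough that the O(dt) weight bias stays inside the band.
  mu <- underdamped_model(fixture_potential("double_well"), beta = 4)
  g <- time_grid(0, 0.5, dt = 1 / 160)
  qs <- seq(-3, 3, length.out = 31)
  ps <- seq(-1.6, 1.6, length.out = 17)
  grd <- expand.grid(q = qs, p = ps)
  Zq <- integrate(function(q) exp(-(q - 1)^4), -Inf, Inf)$value
  est <- fp_density_underdamped(grd, 0.5, mu, g, function(q, p)
    -(q - 1)^4 - log(Zq) + dnorm(p, sd = 0.5, log = TRUE),
    M = 3e3, rng = rng_stream(BASE_SEED))
  wide <- matrix(est$mean, nrow = 31)
  mass_q <- apply(wide, 1, function(r) bridgemc:::trapz(ps, r))
  mass <- bridgemc:::trapz(qs, mass_q)
  expect_lt(abs(mass - 1), 0.05)
})

test_that("a static stiff potential relaxes toward the Gibbs density", {
  m <- overdamped_model(fixture_potential("cubic_grad"))
  eq <- equilibrium_density(fixture_potential("cubic_grad"))
  pts <- seq(-2, 2, length.out = 21)
  gfull <- time_grid(0, 0.75, dt = 5e-3)
  l1_at <- function(t) {
    est <- fp_density_overdamped(pts, t, m, gfull,
                                 function(q) dnorm(q, log = TRUE),
                                 M = 4e3, rng = rng_stream(BASE_SEED),
                                 normalize = TRUE)
    ref <- eq(pts); ref <- ref / bridgemc:::trapz(pts, ref)
    sum(ref * abs(est$mean - ref))
  }
  early <- l1_at(0.15)
  late <- l1_at(0.75)
  expect_lt(late, early)
  expect_lt(late, 0.3)
})

test_that("diagnostic norms implement the caption formulas", {
  est <- tibble::tibble(q = c(0, 1), mean = c(0.6, 0.4), se = c(0.01, 0.02))
  class(est) <- c("density_estimate", class(est))
  d <- density_diagnostics(est, c(0.5, 0.5))
  expect_equal(d$l1, 0.1)
  expect_equal(d$l2, sqrt(0.5 * 0.01 + 0.5 * 0.01))
  expect_equal(d$linf, 0.01)
  expect_equal(d$max_variance, 4e-4)
  # identical estimate: all norms vanish
  est$mean <- c(0.5, 0.5)
  d0 <- density_diagnostics(est, c(0.5, 0.5))
  expect_equal(unlist(d0[c("l1", "l2", "linf")]), c(l1 = 0, l2 = 0, linf = 0))
  expect_error(density_diagnostics(est, c(0.5, 0.5, 0.5)), "point set")
})

test_that("error norms shrink with the trajectory budget on average", {
  g <- time_grid(0, 0.3, n = 30)
  pts <- seq(-1.5, 1.5, length.out = 11)
  ref <- dnorm(pts, sd = sqrt(1 + 2 * 0.3))
  l1_of <- function(M, s) {
    est <- fp_density_overdamped(pts, 0.3, ovd_zero(), g,
                                 function(q) dnorm(q, log = TRUE), M = M,
                                 rng = rng_stream(s), share_noise = FALSE)
    density_diagnostics(est, ref)$l1
  }
  small <- mean(vapply(1:8, function(s) l1_of(60, s), 0))
  big <- mean(vapply(1:8, function(s) l1_of(1500, s), 0))
  expect_lt(big, small)
})

test_that("box-filter smoothing behaves like the figure convolution", {
  expect_equal(smooth_density(c(1, 4, 2, 8), 1), c(1, 4, 2, 8))
  expect_equal(smooth_density(rep(3, 7), 5), rep(3, 7))
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(smooth_density(imp, 3), c(0, 0, 1, 1, 1, 0, 0) / 3)
  # interior mass preserved under trapezoid quadrature
  x <- seq(0, 1, length.out = 41)
  y <- exp(-(x - 0.5)^2 / 0.005)
  expect_lt(abs(bridgemc:::trapz(x, smooth_density(y, 5)) -
                  bridgemc:::trapz(x, y)), 1e-12)
  expect_error(smooth_density(imp, 4), "odd")
})
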