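test_that("boundary marginals are normalized on the box", {
  b <- boundary_conditions(function(q) (q - 1)^4 / 4,
                           function(q) (q^2 - 1)^2 / 4)
  qq <- seq(-6, 6, length.out = 4001)
  expect_lt(abs(bridgemc:::trapz(qq, b$Pi(qq)) - 1), 1e-3)
  expect_lt(abs(bridgemc:::trapz(qq, b$Pf(qq)) - 1), 1e-3)
  expect_equal(b$log_Pi(0.5), log(b$Pi(0.5)))
})

test_that("heat propagation is the Gaussian smoothing identity", {
  m <- ovd_zero()
  pts <- seq(-6, 6, length.out = 401)
  lv <- dnorm(pts, sd = 0.8, log = TRUE)
  # zero step: identity
  expect_identical(heat_propagate(lv, pts, 0, m), lv)
  # constant input: exactly constant output (kernel has unit mass)
  const <- rep(1.7, length(pts))
  out <- heat_propagate(const, pts, 0.05, m, M = 200,
                        rng = rng_stream(BASE_SEED))
  expect_equal(out, const, tolerance = 1e-12)
  # Gaussian input: the smoothing identity is the Gaussian convolution, so
  # the density profile widens to variance s^2 + 2 mu dt / beta
  out2 <- heat_propagate(lv, pts, 0.1, m, M = 4e3,
                         rng = rng_stream(BASE_SEED))
  s2 <- 0.8^2 + 2 * 0.1
  ref0 <- dnorm(0, sd = sqrt(s2))  # value at q = 0
  mid <- which(pts == 0)
  se <- 3 * sd(exp(lv)) / sqrt(4e3)  # loose MC bound
  expect_lt(abs(exp(out2[mid]) - ref0), se + 5e-3)
  # quadrature method agrees tightly with the closed form
  out3 <- heat_propagate(lv, pts, 0.1, m, method = "quadrature", n_quad = 41)
  expect_lt(abs(exp(out3[mid]) - ref0), 2e-3)
  expect_error(heat_propagate(lv, pts, -0.1, m), "non-negative")
})

test_that("heat propagation composes as a semigroup", {
  m <- ovd_zero()
  pts <- seq(-8, 8, length.out = 801)
  lv <- dnorm(pts, sd = 1, log = TRUE)
  one <- heat_propagate(lv, pts, 0.2, m, method = "quadrature", n_quad = 41)
  two <- heat_propagate(heat_propagate(lv, pts, 0.08, m,
                                       method = "quadrature", n_quad = 41),
                        pts, 0.12, m, method = "quadrature", n_quad = 41)
  expect_lt(max(abs(exp(one) - exp(two))[abs(pts) < 5]), 2e-3)
})

test_that("identical Gaussian marginals give a static bridge", {
  # Pi = Pf = Gibbs of a harmonic potential: the optimal bridge keeps the
  # density fixed in time
  b <- boundary_conditions(function(q) q^2 / 2, function(q) q^2 / 2)
  m <- ovd_zero()
  g <- time_grid(0, 0.2, dt = 0.02)
  pts <- seq(-4, 4, length.out = 161)
  br <- half_bridge_solve(b, m, g, pts, iterations = 6, M = 3e3,
                          rng = rng_stream(BASE_SEED), tol = 1e-4)
  mid <- bridge_density(br, 0.1)
  ref <- b$Pi(pts)
  expect_lt(sum(ref * abs(mid$density - ref)) /
              sum(ref * ref), 0.1)
})

test_that("a single sweep with flat boundaries stays flat in the interior", {
  b <- boundary_conditions(function(q) rep(0, length(q)),
                           function(q) rep(0, length(q)), box = c(-3, 3))
  m <- ovd_zero()
  g <- time_grid(0, 0.1, dt = 0.05)
  pts <- seq(-3, 3, length.out = 121)
  br <- half_bridge_solve(b, m, g, pts, iterations = 1, M = 2e3,
                          rng = rng_stream(BASE_SEED))
  mid <- bridge_density(br, 0.05)
  inner <- abs(pts) < 2
  dev <- abs(mid$density[inner] / mean(mid$density[inner]) - 1)
  expect_lt(max(dev), 0.05)
})

test_that("the two-well workflow pins both marginals and closes the loop", {
  b <- boundary_conditions(function(q) (q - 1)^4 / 4,
                           function(q) (q^2 - 1)^2 / 4)
  m <- ovd_zero()
  g <- time_grid(0, 0.2, dt = 0.005)
  pts <- seq(-3, 3, length.out = 200)
  br <- half_bridge_solve(b, m, g, pts, iterations = 10, M = 4e3,
                          rng = rng_stream(BASE_SEED), tol = 1e-4)
  gl <- glance(br)
  # scaled-down run (200 points, 4e3 kernel samples): looser pinning than
  # the full-size workflow exercised in the acceptance suite
  expect_lt(gl$l1_initial, 0.25)
  expect_lt(gl$l1_final, 0.25)
  # stationarity: the BEL gradient of the reconstructed value function
  # matches the bridge drift through grad U = (2/beta) grad V
  dyn <- overdamped_model(bridge_potential(br))
  probe <- seq(-1.5, 1.5, length.out = 7)
  Vtf <- function(q) approx(br$points, br$V[nrow(br$V), ], xout = q,
                            rule = 2)$y
  gr <- bel_gradient_overdamped(probe, 0, dyn, g, Vtf, "bridge", M = 3e3,
                                rng = rng_stream(BASE_SEED + 1))
  dU0 <- approx(br$points, br$dU[1, ], xout = probe)$y
  res <- stationarity_residual(
    tibble::tibble(q = probe, dU = dU0, dV = gr$estimate), beta = 1)
  expect_lt(glance(res)$mean_abs, 0.15)
  # tidy layout
  td <- tidy(br)
  expect_equal(nrow(td), length(pts) * length(g$nodes))
  expect_true(all(td$p >= 0))
})

test_that("the half-bridge iteration converges to the assigned marginals", {
  # the two-well pair on horizon 0.2 is weakly coupled (kernel width ~0.63
  # vs well separation ~2), so the proportional-fitting map converges at a
  # slow geometric rate (~0.65 per sweep); with noise-free quadrature
  # propagation the marginal error is percent-level after 10 sweeps and
  # drops three orders of magnitude by 40 sweeps
  bounds <- boundary_conditions(function(q) (q - 1)^4 / 4,
                                function(q) (q^2 - 1)^2 / 4)
  m <- ovd_zero()
  g <- time_grid(0, 0.2, dt = 0.005)
  wide <- seq(-6, 6, length.out = 301)
  probe <- seq(-3, 3, length.out = 200)
  Pfp <- bounds$Pf(probe)
  l1_at <- function(iters) {
    br <- half_bridge_solve(bounds, m, g, wide, iterations = iters, M = 1,
                            rng = rng_stream(BASE_SEED), tol = 0,
                            method = "quadrature")
    cand <- br$p_tf_candidate / bridgemc:::trapz(wide, br$p_tf_candidate)
    sum(Pfp * abs(approx(wide, cand, probe)$y - Pfp))
  }
  ten <- l1_at(10)
  forty <- l1_at(40)
  expect_lt(forty, 0.02)
  expect_lt(forty, ten / 20)
})

test_that("the KL control cost has its closed-form special cases", {
  m <- ovd_zero()
  g <- time_grid(0, 0.5, n = 25)
  # zero drift: exactly zero
  k0 <- kl_cost(fixture_potential("zero"), m, g, sample_init = rnorm,
                M = 100, rng = rng_stream(BASE_SEED))
  expect_equal(k0$estimate, 0)
  expect_equal(k0$se, 0)
  # constant drift c: (beta mu / 4) c^2 T exactly, zero variance
  cpot <- potential(gradient = function(t, q) rep(1.5, length(q)),
                    hessian = function(t, q) rep(0, length(q)))
  kc <- kl_cost(cpot, m, g, sample_init = rnorm, M = 100,
                rng = rng_stream(BASE_SEED))
  expect_equal(kc$estimate, 0.25 * 1.5^2 * 0.5, tolerance = 1e-12)
  expect_equal(kc$se, 0)
  # harmonic drift from the stationary law: independent moment quadrature
  k <- 1
  hpot <- fixture_potential("harmonic", k = k)
  sampler <- function(n) rnorm(n, sd = 1)  # stationary at beta k = 1
  kh <- kl_cost(hpot, m, g, sample_init = sampler, M = 2e4,
                rng = rng_stream(BASE_SEED))
  # OU from stationarity stays stationary: E |k q_t|^2 = k^2 / (beta k)
  ref <- 0.25 * 1 * 0.5
  expect_within_3se(kh$estimate, ref, kh$se, slack = 5e-3)
})

test_that("stationarity residual is plain arithmetic on the fields", {
  d <- tibble::tibble(q = 1:3, dU = c(1, 2, 3), dV = c(0.5, 1, 1.4))
  r <- stationarity_residual(d, beta = 1)
  expect_equal(r$residual, c(1, 2, 3) - 2 * c(0.5, 1, 1.4))
  exact <- stationarity_residual(
    tibble::tibble(dU = c(2, 4), dV = c(1, 2)), beta = 1)
  expect_equal(exact$residual, c(0, 0))
  expect_error(stationarity_residual(tibble::tibble(dU = 1), beta = 1))
})

test_that("the inverse-CDF sampler reproduces its target density", {
  x <- sample_density(function(q) dnorm(q, log = TRUE), c(-6, 6), 2e4,
                      rng = rng_stream(BASE_SEED))
  expect_lt(abs(mean(x)), 0.03)
  expect_lt(abs(sd(x) - 1), 0.03)
})
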