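# Closed-form solutions and brute-force oracles. Everything here is
# implemented without reference to the Monte Carlo estimators it is used to
# test: the only shared ingredient is the random stream.

#' Ornstein-Uhlenbeck transition density (overdamped quadratic potential)
#'
#' For `U = k q^2 / 2` the overdamped diffusion is an Ornstein-Uhlenbeck
#' process with exact Gaussian transitions: mean `q0 exp(-mu k (t - s))` and
#' variance `(1 / (beta k)) (1 - exp(-2 mu k (t - s)))`; for `k = 0` the heat
#' kernel with variance `2 mu (t - s) / beta`.
#'
#' @param q Evaluation point(s).
#' @param t Target time.
#' @param q0 Starting point.
#' @param s Starting time, `< t`.
#' @param k Stiffness (`>= 0`).
#' @param mu,beta Model constants.
#' @return Density values at `q`.
#' @export
ou_overdamped_transition <- function(q, t, q0, s, k = 1, mu = 1, beta = 1) {
  abort_if(t <= s, "`t` must exceed `s`.")
  abort_if(k < 0, "`k` must be non-negative.")
  if (k == 0) {
    v <- 2 * mu * (t - s) / beta
    m <- q0
  } else {
    e <- exp(-mu * k * (t - s))
    m <- q0 * e
    v <- (1 - e^2) / (beta * k)
  }
  stats::dnorm(q, mean = m, sd = sqrt(v))
}

#' Gaussian phase-space law
#' @param mean Mean vector.
#' @param cov Covariance matrix.
#' @export
gaussian_law <- function(mean, cov) {
  cov <- as.matrix(cov)
  abort_if(length(mean) != nrow(cov) || nrow(cov) != ncol(cov),
           "dimension mismatch.")
  abort_if(max(abs(cov - t(cov))) > 1e-10, "`cov` must be symmetric.")
  structure(list(mean = as.numeric(mean), cov = (cov + t(cov)) / 2),
            class = "gaussian_law")
}

#' Density of a Gaussian law
#' @param law A [gaussian_law()].
#' @param x Evaluation points: vector (one point) or matrix (rows).
#' @export
gaussian_density <- function(law, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  k <- length(law$mean)
  Ci <- solve(law$cov)
  dev <- sweep(X, 2, law$mean)
  qf <- rowSums((dev %*% Ci) * dev)
  exp(-qf / 2) / sqrt((2 * pi)^k * det(law$cov))
}

#' Exact law of the eta-regularized linear phase-space system
#'
#' The linear system with friction on the momentum, coupling `dq = p/m dt`
#' plus an independent position noise of strength `eta`, has the explicit
#' solution `p_t = p0 exp(-T/tau) + (noise)`,
#' `q_t = q0 + integral of p/m + eta-noise`. The mean follows directly; the
#' covariance is assembled by one-dimensional quadrature of the explicit
#' noise kernels (independent of any path simulation):
#' `K_p(u) = sqrt(2m/(beta tau)) exp(-(T-u)/tau)`,
#' `K_q(u) = (tau/m) sqrt(2m/(beta tau)) (1 - exp(-(T-u)/tau))`,
#' plus the constant kernel `eta sqrt(2 tau/(m beta))` on the position's own
#' noise channel.
#'
#' @param x0 Starting phase point `c(q0, p0)`.
#' @param T_ Elapsed time `t - s >= 0`.
#' @param m,tau,beta Model constants.
#' @param eta Position-noise regularization (0 recovers the degenerate
#'   underdamped system).
#' @return A [gaussian_law()] on `(q, p)`.
#' @export
linear_underdamped_solution <- function(x0, T_, m = 1, tau = 1, beta = 1,
                                        eta = 0) {
  abort_if(T_ < 0, "`T_` must be non-negative.")
  q0 <- x0[1]; p0 <- x0[2]
  if (T_ == 0) return(gaussian_law(c(q0, p0), matrix(0, 2, 2)))
  e <- exp(-T_ / tau)
  mean <- c(q0 + p0 * tau / m * (1 - e), p0 * e)
  cp <- sqrt(2 * m / (beta * tau))
  Kp <- function(u) cp * exp(-(T_ - u) / tau)
  Kq <- function(u) (tau / m) * cp * (1 - exp(-(T_ - u) / tau))
  vp <- stats::integrate(function(u) Kp(u)^2, 0, T_, rel.tol = 1e-10)$value
  vq <- eta^2 * (2 * tau / (m * beta)) * T_ +
    stats::integrate(function(u) Kq(u)^2, 0, T_, rel.tol = 1e-10)$value
  cqp <- stats::integrate(function(u) Kq(u) * Kp(u), 0, T_,
                          rel.tol = 1e-10)$value
  gaussian_law(mean, matrix(c(vq, cqp, cqp, vp), 2, 2))
}

#' Push a Gaussian initial law through the linear phase-space flow
#'
#' For a Gaussian initial joint law the time-`T` marginal of the linear
#' system is again Gaussian: `x_T = F x_0 + G` with deterministic
#' `F = [[1, (tau/m)(1 - e)], [0, e]]`, `e = exp(-T/tau)`, and `G` the
#' centred Gaussian of [linear_underdamped_solution()].
#'
#' @param law0 Initial [gaussian_law()] on `(q, p)`.
#' @inheritParams linear_underdamped_solution
#' @return The time-`T` [gaussian_law()].
#' @export
linear_underdamped_pushforward <- function(law0, T_, m = 1, tau = 1, beta = 1,
                                           eta = 0) {
  e <- exp(-T_ / tau)
  F_ <- matrix(c(1, 0, tau / m * (1 - e), e), 2, 2)
  noise <- linear_underdamped_solution(c(0, 0), T_, m, tau, beta, eta)
  gaussian_law(as.numeric(F_ %*% law0$mean),
               F_ %*% law0$cov %*% t(F_) + noise$cov)
}

#' Closed-form momentum gradient of the linear value problem
#'
#' For terminal cost `phi(x) = p` on the linear system the value function is
#' `V_t(p, q) = p exp(-(tf - t)/tau)`, so the momentum gradient is
#' `exp(-(tf - t)/tau)` independently of the state and of the
#' regularization.
#'
#' @param t Evaluation time.
#' @param tf Terminal time, `>= t`.
#' @param tau Stokes time.
#' @export
linear_value_gradient <- function(t, tf, tau = 1) {
  abort_if(tf < t, "`tf` must be >= `t`.")
  exp(-(tf - t) / tau)
}

#' Common-random-number finite-difference gradient of a Dynkin value
#'
#' The master oracle for the Bismut-Elworthy-Li estimators: a central finite
#' difference of [dynkin_value()] in one state direction, with the *same*
#' noise draws used at both displaced starting points, so the Monte Carlo
#' error of the difference is that of the per-path pathwise difference
#' rather than of two independent estimates.
#'
#' @param x Starting state.
#' @param time Start time (grid node).
#' @param problem A [value_problem()].
#' @param grid A [time_grid()].
#' @param direction Component index to differentiate.
#' @param step Displacement `h` (the estimate carries an `O(h^2)` bias).
#' @param M Number of paths.
#' @param rng An [rng_stream()].
#' @return A one-row tibble: `estimate`, `se`, `M`, `step`.
#' @export
fd_gradient_dynkin <- function(x, time, problem, grid, direction = 1L,
                               step = 1e-2, M = 1e4, rng = rng_stream(1)) {
  abort_if(step <= 0, "`step` must be positive.")
  i <- grid_index(grid, time)
  nn <- length(grid$nodes)
  abort_if(i >= nn, "`time` must be strictly before the final grid node.")
  sub <- time_grid(nodes = grid$nodes[i:nn])
  eps <- noise_array(rng, M, grid_n(sub), problem$dim)
  xp <- xm <- as.numeric(x)
  xp[direction] <- xp[direction] + step
  xm[direction] <- xm[direction] - step
  vp <- dynkin_totals(xp, sub, problem, M, noises = eps)
  vm <- dynkin_totals(xm, sub, problem, M, noises = eps)
  diffs <- (vp - vm) / (2 * step)
  tibble::tibble(estimate = mean(diffs), se = stats::sd(diffs) / sqrt(M),
                 M = M, step = step)
}

#' Equilibrium (Gibbs) density of a static potential
#'
#' `exp(-beta U(q)) / Z` with `Z` from trapezoid quadrature on a box; the
#' long-time limit of the overdamped dynamics under a time-independent
#' confining potential.
#'
#' @param pot A [potential()] with a `value` accessor (time-independent use).
#' @param beta Inverse temperature.
#' @param box Quadrature interval.
#' @param n_quad Quadrature nodes.
#' @return A vectorized density function of `q`.
#' @export
equilibrium_density <- function(pot, beta = 1, box = c(-6, 6), n_quad = 2001) {
  qq <- seq(box[1], box[2], length.out = n_quad)
  Z <- trapz(qq, exp(-beta * pot_value(pot, 0, qq)))
  function(q) exp(-beta * pot_value(pot, 0, q)) / Z
}
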