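#' Boundary conditions of a Schrödinger bridge
#'
#' Initial and final marginals of Gibbs form,
#' `P_i(q) = exp(-beta U_i(q)) / Z_i` and `P_f(q) = exp(-beta U_f(q)) / Z_f`,
#' with the normalization constants computed by trapezoid quadrature over a
#' declared box.
#'
#' @param U_i,U_f Boundary potentials: vectorized functions of `q`.
#' @param beta Inverse temperature.
#' @param box Length-2 quadrature interval (must contain essentially all
#'   mass).
#' @param n_quad Number of quadrature nodes.
#' @return An object of class `bridge_bounds` with vectorized accessors
#'   `log_Pi`, `log_Pf`, `Pi`, `Pf`.
#' @export
boundary_conditions <- function(U_i, U_f, beta = 1, box = c(-6, 6),
                                n_quad = 2001) {
  abort_if(!is.function(U_i) || !is.function(U_f),
           "`U_i` and `U_f` must be functions of q.")
  abort_if(length(box) != 2 || box[2] <= box[1], "`box` must be c(lo, hi).")
  qq <- seq(box[1], box[2], length.out = n_quad)
  logZ_i <- log(trapz(qq, exp(-beta * U_i(qq))))
  logZ_f <- log(trapz(qq, exp(-beta * U_f(qq))))
  structure(list(
    log_Pi = function(q) -beta * U_i(q) - logZ_i,
    log_Pf = function(q) -beta * U_f(q) - logZ_f,
    Pi = function(q) exp(-beta * U_i(q) - logZ_i),
    Pf = function(q) exp(-beta * U_f(q) - logZ_f),
    beta = beta, box = box, U_i = U_i, U_f = U_f),
    class = "bridge_bounds")
}

# Piecewise-linear interpolation of log values with linear tail extrapolation
# (quartic boundary potentials decay fast; constant extrapolation would
# overweight the tails).
log_interp <- function(x, y) {
  n <- length(x)
  sl_lo <- (y[2] - y[1]) / (x[2] - x[1])
  sl_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  function(xq) {
    out <- approx(x, y, xout = xq, rule = 2)$y
    lo <- xq < x[1]; hi <- xq > x[n]
    if (any(lo)) out[lo] <- y[1] + sl_lo * (xq[lo] - x[1])
    if (any(hi)) out[hi] <- y[n] + sl_hi * (xq[hi] - x[n])
    out
  }
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of f(y) exp(-y^2)).
gauss_hermite <- function(n) {
  b <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- b
  J[cbind(2:n, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Heat-kernel propagation of a bridge potential
#'
#' One time step of the linear half-bridge equations: both `phi` (propagated
#' from the final toward the initial time) and `phihat` (initial toward
#' final) satisfy, in their own orientation, the smoothing identity
#' `value(q) <- E[value(q + sqrt(2 mu dt / beta) * xi)]`, `xi ~ N(0, 1)`.
#' Values are carried in log space and the average is a log-sum-exp; off-grid
#' evaluation uses linear interpolation of the log values with linear tail
#' extrapolation.
#'
#' @param log_values Log values at `points` (sorted ascending).
#' @param points Ordered 1-d query grid.
#' @param dt Time-step length, `> 0` (0 is allowed and is the identity).
#' @param model An [overdamped_model()] (supplies `mu`, `beta`).
#' @param method `"mc"` (Monte Carlo: `M` shared normal draws, taken as
#'   antithetic pairs since the kernel is symmetric) or `"quadrature"`
#'   (Gauss-Hermite, `n_quad` nodes).
#' @param M Monte Carlo sample count.
#' @param rng An [rng_stream()] (MC method).
#' @param n_quad Gauss-Hermite node count.
#' @return Log values at `points` after the step.
#' @export
heat_propagate <- function(log_values, points, dt, model,
                           method = c("mc", "quadrature"), M = 1e3,
                           rng = rng_stream(1), n_quad = 31) {
  method <- match.arg(method)
  abort_if(dt < 0, "`dt` must be non-negative.")
  if (dt == 0) return(log_values)
  sigma <- sqrt(2 * model$mu * dt / model$beta)
  f <- log_interp(points, log_values)
  if (method == "mc") {
    # antithetic pairs: the kernel is symmetric, so +/- xi cancels the odd
    # component of the sampling error at no extra cost
    half <- as.numeric(noise_array(rng, 1, ceiling(M / 2), 1))
    xi <- c(half, -half)
    Q <- outer(points, sigma * xi, "+")
    L <- matrix(f(as.numeric(Q)), nrow = length(points))
    row_logmeanexp(L)
  } else {
    gh <- gauss_hermite(n_quad)
    Q <- outer(points, sigma * sqrt(2) * gh$nodes, "+")
    L <- matrix(f(as.numeric(Q)), nrow = length(points))
    lw <- log(gh$weights) - 0.5 * log(pi)
    apply(sweep(L, 2, lw, "+"), 1, logsumexp)
  }
}

#' Iterative half-bridge solution of the overdamped Schrödinger bridge
#'
#' Solves for the pair of bridge potentials `(phi, phihat)` whose product
#' reconstructs the entropically optimal density `p_t = phi_t * phihat_t`
#' steering `P_i` into `P_f` while minimizing the Kullback-Leibler divergence
#' from a free diffusion. Starting from the flat guess `phi = 1`, each sweep
#' alternates: set `phihat_ti = P_i / phi_ti` and carry `phihat` to the final
#' time; reset `phi_tf = P_f / phihat_tf` and carry `phi` back — repeating
#' until the reconstructed final density stops changing (relative l1) or the
#' iteration cap is reached. The value function is `V_t = -log phi_t` and the
#' optimal drift follows from the stationarity relation
#' `grad U_t = (2 / beta) grad V_t`.
#'
#' @param bounds A [boundary_conditions()].
#' @param model An [overdamped_model()] (its potential is not used; `mu` and
#'   `beta` set the kernel width).
#' @param grid A [time_grid()] over the control horizon.
#' @param points Ordered 1-d evaluation grid (shared by `phi` and `phihat`).
#' @param iterations Sweep cap.
#' @param M Monte Carlo samples per propagation step.
#' @param rng An [rng_stream()].
#' @param tol Relative-l1 convergence threshold on successive `p_tf`.
#' @param method Propagation method, see [heat_propagate()].
#' @return An object of class `sb_bridge`; see [tidy.sb_bridge()] and
#'   [glance.sb_bridge()].
#' @export
half_bridge_solve <- function(bounds, model, grid, points, iterations = 10,
                              M = 1e4, rng = rng_stream(1), tol = 1e-3,
                              method = "mc") {
  abort_if(!inherits(bounds, "bridge_bounds"), "need boundary_conditions().")
  abort_if(iterations < 1, "`iterations` must be >= 1.")
  abort_if(any(diff(points) <= 0), "`points` must be strictly increasing.")
  N <- grid_n(grid); P <- length(points)
  CAP <- 700  # floor/ceiling on log potentials after half-bridge division
  floor_count <- 0L
  log_phi <- matrix(0, N + 1, P)
  log_phh <- matrix(-Inf, N + 1, P)
  clamp <- function(x) {
    bad <- !is.finite(x) | abs(x) > CAP
    floor_count <<- floor_count + sum(bad & x > -Inf)
    pmin(pmax(x, -CAP), CAP)
  }
  conv <- numeric(0)
  p_tf_prev <- NULL
  it_run <- 0L
  for (it in seq_len(iterations)) {
    it_run <- it
    log_phh[1, ] <- clamp(bounds$log_Pi(points) - log_phi[1, ])
    for (n in seq_len(N)) {
      log_phh[n + 1, ] <- heat_propagate(log_phh[n, ], points, grid$dt[n],
                                         model, method = method, M = M,
                                         rng = rng_spawn(rng, 2L * it * N + n))
    }
    # Pre-reset reconstruction of the final density: phi still carries the
    # previous sweep's backward solution, so this is the genuine residual of
    # the iteration (after the reset below, phi_tf * phihat_tf = P_f by
    # construction and would be useless as a convergence signal).
    p_tf <- exp(log_phi[N + 1, ] + log_phh[N + 1, ])
    log_phi[N + 1, ] <- clamp(bounds$log_Pf(points) - log_phh[N + 1, ])
    for (n in N:1) {
      log_phi[n, ] <- heat_propagate(log_phi[n + 1, ], points, grid$dt[n],
                                     model, method = method, M = M,
                                     rng = rng_spawn(rng, (2L * it + 1) * N + n))
    }
    done <- FALSE
    if (!is.null(p_tf_prev)) {
      rel <- sum(abs(p_tf - p_tf_prev)) / max(sum(abs(p_tf_prev)), 1e-300)
      conv <- c(conv, rel)
      done <- rel < tol
    }
    p_tf_prev <- p_tf
    if (done) break
  }
  log_p <- log_phi + log_phh
  V <- -log_phi
  # Drift from the stationarity relation: grad U = (2/beta) grad V, with
  # grad V = -d/dq log phi by central differences on the point grid.
  dV <- t(apply(log_phi, 1, function(y) -num_grad(points, y)))
  dU <- (2 / model$beta) * dV
  structure(list(points = points, grid = grid, log_phi = log_phi,
                 log_phihat = log_phh, log_p = log_p, V = V, dV = dV, dU = dU,
                 p_tf_candidate = p_tf_prev,
                 bounds = bounds, model = model, iterations = it_run,
                 convergence = conv, floor_count = floor_count),
            class = "sb_bridge")
}

# Central finite differences on a (possibly non-uniform) grid.
num_grad <- function(x, y) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

#' @export
print.sb_bridge <- function(x, ...) {
  cat(sprintf("<sb_bridge: %d points, %d nodes, %d sweeps%s>\n",
              length(x$points), length(x$grid$nodes), x$iterations,
              if (x$floor_count > 0)
                sprintf(", %d floored divisions", x$floor_count) else ""))
  invisible(x)
}

#' Reconstructed density of a solved bridge at one time node
#'
#' @param bridge An `sb_bridge`.
#' @param time A grid node.
#' @param normalize Rescale to unit trapezoid mass over the point grid
#'   (default `TRUE`, the figure-style convention for interior times).
#' @return A tibble `q`, `density`.
#' @export
bridge_density <- function(bridge, time, normalize = TRUE) {
  n <- grid_index(bridge$grid, time)
  dens <- exp(bridge$log_p[n, ])
  if (normalize) dens <- dens / trapz(bridge$points, dens)
  tibble::tibble(q = bridge$points, density = dens)
}

#' Interpolated drift field of a solved bridge
#'
#' Returns the bridge's optimal mechanical force `grad U_t(q)` as a
#' [potential()] (gradient and Hessian accessors; the Hessian is the
#' derivative of the interpolated gradient), linear in time between grid
#' nodes and linear in `q` with tail extrapolation. Usable directly as the
#' driving potential of the Fokker-Planck and value-gradient estimators.
#'
#' @param bridge An `sb_bridge`.
#' @return A [potential()].
#' @export
bridge_potential <- function(bridge) {
  pts <- bridge$points; nodes <- bridge$grid$nodes
  dU <- bridge$dU
  d2U <- t(apply(dU, 1, function(y) num_grad(pts, y)))
  interp_t <- function(tab, t, q) {
    t <- min(max(t, nodes[1]), nodes[length(nodes)])
    j <- findInterval(t, nodes, rightmost.closed = TRUE)
    j <- min(j, length(nodes) - 1)
    w <- (t - nodes[j]) / (nodes[j + 1] - nodes[j])
    y <- (1 - w) * tab[j, ] + w * tab[j + 1, ]
    log_interp(pts, y)(q)  # linear interpolation with tail extension
  }
  potential(
    gradient = function(t, q) interp_t(dU, t, q),
    hessian = function(t, q) interp_t(d2U, t, q),
    d = 1L)
}

#' Kullback-Leibler control cost of a drift
#'
#' The divergence of the controlled diffusion from a free diffusion,
#' `KL = (beta mu / 4) E int_ti^tf |grad U_t(q_t)|^2 dt`,
#' estimated over forward overdamped paths driven by the drift itself and
#' started from samples of the initial marginal; the time integral uses the
#' trapezoid rule.
#'
#' @param drift_potential A [potential()] supplying `grad U` (e.g. from
#'   [bridge_potential()]).
#' @param model An [overdamped_model()] (supplies `mu`, `beta`).
#' @param grid A [time_grid()].
#' @param sample_init Function `n -> numeric(n)` drawing from the initial
#'   marginal, or a numeric vector of pre-drawn initial positions.
#' @param M Number of paths.
#' @param rng An [rng_stream()].
#' @return A one-row tibble: `estimate`, `se`, `M`.
#' @export
kl_cost <- function(drift_potential, model, grid, sample_init, M = 1e4,
                    rng = rng_stream(1)) {
  q0 <- if (is.function(sample_init)) {
    with_rng(rng_spawn(rng, 1L), sample_init(M))
  } else {
    rep_len(sample_init, M)
  }
  mod <- overdamped_model(drift_potential, mu = model$mu, beta = model$beta)
  batch <- simulate_overdamped_forward(matrix(q0, ncol = 1), grid, mod, M,
                                       rng_spawn(rng, 2L))
  N <- grid_n(grid)
  g2 <- matrix(0, M, N + 1)
  for (n in seq_len(N + 1)) {
    g <- pot_grad(drift_potential, grid$nodes[n],
                  matrix(batch$states[, n, ], nrow = M))
    g2[, n] <- rowSums(g * g)
  }
  w <- c(grid$dt / 2, 0) + c(0, grid$dt / 2)  # trapezoid weights
  per_path <- (model$beta * model$mu / 4) * as.numeric(g2 %*% w)
  tibble::tibble(estimate = mean(per_path),
                 se = stats::sd(per_path) / sqrt(M), M = M)
}

#' Stationarity residual between a drift and a value gradient
#'
#' First-order optimality of the bridge links the optimal mechanical force to
#' the value function through `grad U = (2 / beta) grad V`. This helper
#' tabulates the pointwise residual `r = grad U - (2 / beta) grad V` over a
#' probe set.
#'
#' @param data A data frame with columns `dU` and `dV` (any extra columns,
#'   e.g. `q` or `time`, are carried through).
#' @param beta Inverse temperature.
#' @return The input tibble with a `residual` column, class
#'   `stationarity_residual`; [glance()] gives `max_abs` and `mean_abs`.
#' @export
stationarity_residual <- function(data, beta) {
  abort_if(!is.data.frame(data) || !all(c("dU", "dV") %in% names(data)),
           "`data` must have columns `dU` and `dV`.")
  out <- tibble::as_tibble(data)
  out$residual <- out$dU - (2 / beta) * out$dV
  class(out) <- c("stationarity_residual", class(out))
  out
}

#' @method glance stationarity_residual
#' @export
glance.stationarity_residual <- function(x, ...) {
  tibble::tibble(max_abs = max(abs(x$residual)),
                 mean_abs = mean(abs(x$residual)),
                 n = nrow(x))
}

#' Inverse-CDF sampler for a 1-d density on a box
#'
#' @param log_density Vectorized log-density function (or
#'   [initial_density()]).
#' @param box Length-2 support interval.
#' @param n Number of draws.
#' @param rng An [rng_stream()].
#' @param n_grid CDF grid resolution.
#' @return `n` draws.
#' @export
sample_density <- function(log_density, box, n, rng = rng_stream(1),
                           n_grid = 4096) {
  f <- as_log_density(log_density)
  qq <- seq(box[1], box[2], length.out = n_grid)
  dens <- exp(f(qq))
  cdf <- cumsum(c(0, (dens[-1] + dens[-n_grid]) / 2 * diff(qq)))
  cdf <- cdf / cdf[n_grid]
  u <- rng_runif(rng, n)
  approx(cdf, qq, xout = u, ties = "ordered", rule = 2)$y
}
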