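#' General value-function problems
#'
#' Describes the terminal-value problem
#' `(d/dt + <b, dx> + <A A^T, dx (x) dx>) V = -F`, `V_tf = phi`,
#' whose Feynman-Kac (Dynkin) representation is a path expectation of the
#' terminal cost plus accumulated running cost along
#' `dx = b_t(x) dt + A_t dw`. The drift may be state-dependent; the
#' volatility `A` is assumed state-independent (a function of time only),
#' which covers every diffusion treated by this package - overdamped,
#' underdamped, and the eta-regularized linear systems.
#'
#' @param drift Function `(t, X)`: `X` is an `M x dim` state matrix, returns
#'   `M x dim` drift values.
#' @param volatility A `dim x dim` matrix, scalar (d = 1), or function
#'   `t -> matrix`.
#' @param terminal Function `X -> numeric(M)`, the terminal cost `phi`.
#' @param running_cost Optional function `(t, X) -> numeric(M)`, the running
#'   cost `F`; `NULL` means zero.
#' @param drift_jacobian Function `(t, X) -> M x dim x dim` array (or a
#'   constant `dim x dim` matrix) of state-Jacobians of the drift; required by
#'   the gradient estimators, not by [dynkin_value()].
#' @param dim State dimension.
#' @return An object of class `value_problem`.
#' @export
value_problem <- function(drift, volatility, terminal, running_cost = NULL,
                          drift_jacobian = NULL, dim = 1L) {
  abort_if(!is.function(drift) || !is.function(terminal),
           "`drift` and `terminal` must be functions.")
  vol <- if (is.function(volatility)) volatility else {
    A <- if (is.matrix(volatility)) volatility else diag(volatility, dim)
    function(t) A
  }
  structure(list(drift = drift, volatility = vol, terminal = terminal,
                 running_cost = running_cost, drift_jacobian = drift_jacobian,
                 dim = as.integer(dim)),
            class = "value_problem")
}

# M x dim x dim Jacobian evaluation with constant-matrix convenience.
prob_jac <- function(problem, t, X) {
  abort_if(is.null(problem$drift_jacobian),
           "this estimator needs `drift_jacobian` on the value problem.")
  J <- if (is.function(problem$drift_jacobian)) problem$drift_jacobian(t, X)
       else problem$drift_jacobian
  if (is.matrix(J) && !identical(dim(J), c(nrow(X), 1L, 1L)))
    J <- array(rep(as.numeric(J), each = nrow(X)),
               dim = c(nrow(X), problem$dim, problem$dim))
  if (!is.array(J) || length(dim(J)) != 3)
    J <- array(J, dim = c(nrow(X), problem$dim, problem$dim))
  J
}

#' Wrap an overdamped model as a value problem
#'
#' Builds the Hamilton-Jacobi-Bellman problem whose characteristics are the
#' forward overdamped paths: drift `-mu grad U`, volatility
#' `sqrt(2 mu / beta) I`, and (by default) the Kullback-Leibler bridge running
#' cost `F = (beta mu / 4) |grad U|^2`.
#'
#' @param model An [overdamped_model()].
#' @param terminal Terminal cost `phi(q)` (vectorized function).
#' @param running_cost `"bridge"` (default), `"none"`, or a function
#'   `(t, q) -> numeric`.
#' @return A [value_problem()].
#' @export
overdamped_problem <- function(model, terminal, running_cost = "bridge") {
  pot <- model$potential; mu <- model$mu; beta <- model$beta; d <- model$d
  F_ <- resolve_running_cost(running_cost, function(t, X) {
    g <- pot_grad(pot, t, X)
    (beta * mu / 4) * rowSums(g * g)
  })
  value_problem(
    drift = function(t, X) -mu * pot_grad(pot, t, X),
    volatility = diag(sqrt(2 * mu / beta), d),
    terminal = function(X) as.numeric(terminal(if (d == 1) X[, 1] else X)),
    running_cost = F_,
    drift_jacobian = function(t, X) -mu * pot_hess(pot, t, X),
    dim = d)
}

#' Wrap an underdamped model as a (degenerate) value problem
#'
#' Phase-space Hamilton-Jacobi-Bellman problem along forward Langevin-Kramers
#' paths; volatility is the degenerate block `diag(0, sqrt(2 m / (tau beta)))`,
#' so only [dynkin_value()] and the degenerate gradient estimator apply, not
#' the volatility-inverting one. Default running cost is the underdamped
#' bridge cost `F = (beta tau / (4 m)) |grad U|^2`.
#'
#' @param model An [underdamped_model()].
#' @param terminal Terminal cost `phi(q, p)`, a function of two vectors.
#' @inheritParams overdamped_problem
#' @export
underdamped_problem <- function(model, terminal, running_cost = "bridge") {
  pot <- model$potential; d <- model$d
  m <- model$m; tau <- model$tau; beta <- model$beta
  F_ <- resolve_running_cost(running_cost, function(t, X) {
    g <- pot_grad(pot, t, matrix(X[, seq_len(d)], nrow = nrow(X)))
    (beta * tau / (4 * m)) * rowSums(g * g)
  }, phase = TRUE)
  A <- matrix(0, 2 * d, 2 * d)
  A[d + seq_len(d), d + seq_len(d)] <- diag(sqrt(2 * m / (tau * beta)), d)
  value_problem(
    drift = function(t, X) {
      q <- matrix(X[, seq_len(d)], nrow = nrow(X))
      p <- matrix(X[, d + seq_len(d)], nrow = nrow(X))
      cbind(p / m, -(p / tau + pot_grad(pot, t, q)))
    },
    volatility = A,
    terminal = function(X) as.numeric(terminal(X[, seq_len(d)],
                                               X[, d + seq_len(d)])),
    running_cost = F_,
    drift_jacobian = function(t, X) {
      n <- nrow(X)
      H <- pot_hess(pot, t, matrix(X[, seq_len(d)], nrow = n))
      J <- array(0, dim = c(n, 2 * d, 2 * d))
      for (j in seq_len(d)) J[, j, d + j] <- 1 / m
      J[, d + seq_len(d), seq_len(d)] <- -H
      for (j in seq_len(d)) J[, d + j, d + j] <- -1 / tau
      J
    },
    dim = 2L * d)
}

resolve_running_cost <- function(running_cost, bridge_fun, phase = FALSE) {
  if (is.function(running_cost)) {
    function(t, X) as.numeric(
      if (phase) running_cost(t, X[, 1:(ncol(X) / 2)], X[, -(1:(ncol(X) / 2))])
      else running_cost(t, if (ncol(X) == 1) X[, 1] else X))
  } else if (identical(running_cost, "bridge")) {
    bridge_fun
  } else if (identical(running_cost, "none") || is.null(running_cost)) {
    NULL
  } else rlang::abort("`running_cost` must be \"bridge\", \"none\" or a function.")
}

# Euler-Maruyama paths of a general value_problem, with stored noises.
simulate_problem_paths <- function(x0, grid, problem, M, rng = NULL,
                                   noises = NULL) {
  dm <- problem$dim; N <- grid_n(grid)
  eps <- resolve_noises(noises, rng, M, N, dm)
  states <- array(0, dim = c(M, N + 1, dm))
  states[, 1, ] <- anchor_matrix(x0, M, dm)
  for (n in seq_len(N)) {
    X <- matrix(states[, n, ], nrow = M)
    b <- problem$drift(grid$nodes[n], X)
    A <- problem$volatility(grid$nodes[n])
    E <- matrix(eps[, n, ], nrow = M)
    states[, n + 1, ] <- X + b * grid$dt[n] + sqrt(grid$dt[n]) * (E %*% t(A))
  }
  list(states = states, noises = eps)
}

#' Dynkin (Feynman-Kac) value estimate
#'
#' Estimates `V_t(x) = E[ phi(x_tf) + int_t^tf F_s(x_s) ds | x_t = x ]` by
#' forward Euler-Maruyama sampling from `x` at time `t`; the running cost is
#' accumulated with the left-endpoint rule, matching the pre-point convention
#' of the path generator.
#'
#' @param x Starting state (length `problem$dim`).
#' @param time Start time; a node of `grid`.
#' @param problem A [value_problem()].
#' @param grid A [time_grid()] ending at the terminal time.
#' @param M Number of sampled paths.
#' @param rng An [rng_stream()].
#' @param noises Optional explicit draws (common-random-number evaluations).
#' @return A one-row tibble: `estimate`, `se`, `M`.
#' @export
dynkin_value <- function(x, time, problem, grid, M = 1e4, rng = rng_stream(1),
                         noises = NULL) {
  i <- grid_index(grid, time)
  nn <- length(grid$nodes)
  if (i == nn) {
    v <- problem$terminal(matrix(x, nrow = 1))
    return(tibble::tibble(estimate = v, se = 0, M = M))
  }
  sub <- time_grid(nodes = grid$nodes[i:nn])
  total <- dynkin_totals(x, sub, problem, M, rng, noises)
  tibble::tibble(estimate = mean(total),
                 se = stats::sd(total) / sqrt(M), M = M)
}

# Per-path Dynkin totals phi(x_tf) + sum F dt on the given subgrid.
dynkin_totals <- function(x, sub, problem, M, rng = NULL, noises = NULL) {
  sim <- simulate_problem_paths(x, sub, problem, M, rng, noises)
  N <- grid_n(sub)
  total <- problem$terminal(matrix(sim$states[, N + 1, ], nrow = M))
  if (!is.null(problem$running_cost)) {
    for (n in seq_len(N)) {
      X <- matrix(sim$states[, n, ], nrow = M)
      total <- total + problem$running_cost(sub$nodes[n], X) * sub$dt[n]
    }
  }
  total
}

#' Tangent-flow cocycle along overdamped paths
#'
#' The derivative of the stochastic flow with respect to its initial
#' condition, evaluated at every node of a forward overdamped batch. In one
#' dimension the factor at node `n` is
#' `exp(-mu * sum_{k<n} d2U_{t_k}(q_{t_k}) dt_k)` (the accumulated-exponent
#' form); in higher dimension it is the time-ordered Euler product
#' `prod_k (I - mu * Hess U dt_k)`. The factor at the first node is the
#' identity, and the discrete product construction satisfies the cocycle
#' composition property exactly.
#'
#' @param batch A forward overdamped `trajectory_batch`.
#' @param model The generating [overdamped_model()] (must have a Hessian).
#' @return For d = 1, an `M x (N+1)` matrix of scalar factors; for d > 1 an
#'   `M x (N+1) x d x d` array.
#' @export
tangent_cocycle_overdamped <- function(batch, model) {
  abort_if(batch$kind != "overdamped" || batch$direction != "forward",
           "`batch` must be a forward overdamped batch.")
  M <- dim(batch$states)[1]; N <- grid_n(batch$grid); d <- model$d
  if (d == 1) {
    out <- matrix(1, M, N + 1)
    acc <- numeric(M)
    for (n in seq_len(N)) {
      h <- pot_hess(model$potential, batch$grid$nodes[n],
                    matrix(batch$states[, n, ], nrow = M))[, 1, 1]
      acc <- acc + model$mu * h * batch$grid$dt[n]
      out[, n + 1] <- exp(-acc)
    }
    out
  } else {
    out <- array(0, dim = c(M, N + 1, d, d))
    cur <- array(rep(diag(d), each = M), dim = c(M, d, d))
    out[, 1, , ] <- cur
    for (n in seq_len(N)) {
      H <- pot_hess(model$potential, batch$grid$nodes[n],
                    matrix(batch$states[, n, ], nrow = M))
      nxt <- cur
      for (a in seq_len(d)) for (b in seq_len(d)) {
        acc <- cur[, a, b]
        for (k in seq_len(d)) acc <- acc - model$mu * batch$grid$dt[n] *
            H[, a, k] * cur[, k, b]
        nxt[, a, b] <- acc
      }
      cur <- nxt
      out[, n + 1, , ] <- cur
    }
    out
  }
}

# Shared assembly of the BEL estimator given per-node weight increments
# u[, n] = <sqrt(dt_n) eps_n, A^-1 c_n> (already including A^-1), terminal
# values phi, and running-cost values F at the nodes. `nodes`/`dt` are the
# local subgrid. The s = t node contributes nothing to the running term.
bel_contrib <- function(u, phi_vals, F_vals, nodes, dt) {
  N <- ncol(u)
  t0 <- nodes[1]; tf <- nodes[N + 1]
  # I[, n] = integral up to node n
  I <- if (N == 1) cbind(0, u) else cbind(0, t(apply(u, 1, cumsum)))
  contrib <- phi_vals * I[, N + 1] / (tf - t0)
  if (!is.null(F_vals) && N >= 2) {
    for (n in 2:N) {
      contrib <- contrib + F_vals[, n] * I[, n] * dt[n] / (nodes[n] - t0)
    }
  }
  contrib
}

bel_assemble <- function(u, phi_vals, F_vals, nodes, dt) {
  contrib <- bel_contrib(u, phi_vals, F_vals, nodes, dt)
  tibble::tibble(estimate = mean(contrib),
                 se = stats::sd(contrib) / sqrt(length(contrib)),
                 M = length(contrib))
}

# Per-group mean/se over a contrib vector laid out as P blocks of M paths.
bel_group_stats <- function(contrib, P, M) {
  grp <- rep(seq_len(P), each = M)
  means <- as.numeric(rowsum(contrib, grp)) / M
  sqs <- as.numeric(rowsum(contrib^2, grp)) / M
  vars <- pmax(sqs - means^2, 0) * M / max(M - 1, 1)
  list(mean = means, se = sqrt(vars / M))
}

# Replicate one M x N x d noise block P times along the path axis (common
# random numbers across query points).
rep_noise <- function(eps, P) {
  M <- dim(eps)[1]
  eps[rep(seq_len(M), times = P), , , drop = FALSE]
}

#' Bismut-Elworthy-Li gradient for the overdamped value function
#'
#' Estimates a directional spatial derivative of the Dynkin value
#' `V_t(q) = E[phi(q_tf) + int F]` without differentiating `phi` or `F`:
#' sampled paths are weighted by stochastic integrals of the tangent-flow
#' cocycle against their own Brownian increments, with the inverse volatility
#' `sqrt(beta / (2 mu))` folded into the weights. The default running cost is
#' the Kullback-Leibler bridge cost `(beta mu / 4) |grad U|^2`, so the
#' estimator applies directly to the coupled bridge system.
#'
#' @param q Starting position(s): a numeric vector of query points (d = 1) or
#'   a `P x d` matrix; one estimate is returned per point.
#' @param time Start time (a grid node, strictly before the final node).
#' @param model An [overdamped_model()] (the potential needs a Hessian).
#' @param grid A [time_grid()] ending at the terminal time.
#' @param terminal Terminal cost `phi(q)` (vectorized function).
#' @param running_cost `"bridge"` (default), `"none"`, or `(t, q)` function.
#' @param M Number of sampled paths per query point.
#' @param rng An [rng_stream()].
#' @param direction Component index of the gradient (d = 1: must be 1).
#' @param share_noise Reuse one set of draws across query points (common
#'   random numbers; default `TRUE`), giving smooth gradient profiles.
#' @param noises Optional explicit draws (for common-random-number studies
#'   against [dynkin_value()]); an `M x N x d` array shared by all points.
#' @return A tibble with one row per query point: `q`, `estimate`, `se`, `M`.
#' @export
bel_gradient_overdamped <- function(q, time, model, grid, terminal,
                                    running_cost = "bridge", M = 1e4,
                                    rng = rng_stream(1), direction = 1L,
                                    share_noise = TRUE, noises = NULL) {
  abort_if(!inherits(model, "overdamped_model"), "need an overdamped model.")
  i <- grid_index(grid, time)
  nn <- length(grid$nodes)
  abort_if(i >= nn, "`time` must be strictly before the final grid node.")
  d <- model$d
  pts <- as_state_matrix(q, d)
  P <- nrow(pts)
  sub <- time_grid(nodes = grid$nodes[i:nn])
  N <- grid_n(sub)
  Mt <- P * M
  eps <- if (!is.null(noises)) rep_noise(noises, P)
         else if (share_noise) rep_noise(noise_array(rng, M, N, d), P)
         else noise_array(rng, Mt, N, d)
  anchors <- pts[rep(seq_len(P), each = M), , drop = FALSE]
  batch <- simulate_overdamped_forward(anchors, sub, model, Mt, noises = eps)
  inv_a <- sqrt(model$beta / (2 * model$mu))
  u <- matrix(0, Mt, N)
  co <- tangent_cocycle_overdamped(batch, model)
  if (d == 1) {
    for (n in seq_len(N)) {
      u[, n] <- sqrt(sub$dt[n]) * batch$noises[, n, 1] * inv_a * co[, n]
    }
  } else {
    for (n in seq_len(N)) {
      ci <- matrix(co[, n, , direction], nrow = Mt)  # cocycle column e_i
      E <- matrix(batch$noises[, n, ], nrow = Mt)
      u[, n] <- sqrt(sub$dt[n]) * inv_a * rowSums(E * ci)
    }
  }
  prob <- overdamped_problem(model, terminal, running_cost)
  phi_vals <- prob$terminal(matrix(batch$states[, N + 1, ], nrow = Mt))
  F_vals <- if (!is.null(prob$running_cost)) {
    fv <- matrix(0, Mt, N)
    for (n in seq_len(N)) {
      fv[, n] <- prob$running_cost(sub$nodes[n],
                                   matrix(batch$states[, n, ], nrow = Mt))
    }
    fv
  }
  contrib <- bel_contrib(u, phi_vals, F_vals, sub$nodes, sub$dt)
  st <- bel_group_stats(contrib, P, M)
  tibble::tibble(q = if (d == 1) pts[, 1] else asplit(pts, 1),
                 estimate = st$mean, se = st$se, M = M)
}

#' Bismut-Elworthy-Li gradient for a general non-degenerate diffusion
#'
#' Full matrix-cocycle version: the linearized (variational) flow is
#' propagated alongside each Euler-Maruyama path via
#' `v_{n+1} = v_n + dt_n * (b_*)(t_n, x_n) v_n`, and the directional
#' derivative `<e_i, grad V_t(x)>` is assembled from the stochastic integrals
#' `int <dw_u, A^-1 v_u>` exactly as in the overdamped specialization. The
#' volatility matrix must be invertible; its condition number is checked
#' before inversion.
#'
#' @param x Starting state.
#' @param time Start time (a grid node, strictly before the final node).
#' @param problem A [value_problem()] with `drift_jacobian`.
#' @param grid A [time_grid()] ending at the terminal time.
#' @param M Number of sampled paths.
#' @param rng An [rng_stream()].
#' @param direction Gradient component index in `1:problem$dim`.
#' @param cond_threshold Largest acceptable volatility condition number.
#' @param noises Optional explicit draws.
#' @return A one-row tibble: `estimate`, `se`, `M`.
#' @export
bel_gradient_general <- function(x, time, problem, grid, M = 1e4,
                                 rng = rng_stream(1), direction = 1L,
                                 cond_threshold = 1e8, noises = NULL) {
  i <- grid_index(grid, time)
  nn <- length(grid$nodes)
  abort_if(i >= nn, "`time` must be strictly before the final grid node.")
  dm <- problem$dim
  sub <- time_grid(nodes = grid$nodes[i:nn])
  N <- grid_n(sub)
  sim <- simulate_problem_paths(x, sub, problem, M, rng, noises)
  u <- matrix(0, M, N)
  V <- matrix(0, M, dm)
  V[, direction] <- 1
  for (n in seq_len(N)) {
    A <- problem$volatility(sub$nodes[n])
    kap <- kappa(A, exact = TRUE)
    abort_if(!is.finite(kap) || kap > cond_threshold,
             sprintf("volatility is numerically singular at t = %g (cond %.3g).",
                     sub$nodes[n], kap))
    Ainv <- solve(A)
    X <- matrix(sim$states[, n, ], nrow = M)
    E <- matrix(sim$noises[, n, ], nrow = M)
    u[, n] <- sqrt(sub$dt[n]) * rowSums((E %*% Ainv) * V)
    J <- prob_jac(problem, sub$nodes[n], X)
    inc <- matrix(0, M, dm)
    for (a in seq_len(dm)) for (k in seq_len(dm)) {
      inc[, a] <- inc[, a] + J[, a, k] * V[, k]
    }
    V <- V + sub$dt[n] * inc
  }
  phi_vals <- problem$terminal(matrix(sim$states[, N + 1, ], nrow = M))
  F_vals <- if (!is.null(problem$running_cost)) {
    fv <- matrix(0, M, N)
    for (n in seq_len(N)) {
      fv[, n] <- problem$running_cost(sub$nodes[n],
                                      matrix(sim$states[, n, ], nrow = M))
    }
    fv
  }
  bel_assemble(u, phi_vals, F_vals, sub$nodes, sub$dt)
}
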