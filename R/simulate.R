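#' Sampled trajectory batches
#'
#' All Euler-Maruyama generators return a `trajectory_batch`: the `M` sampled
#' paths on the time grid together with the exact standard-normal draws that
#' generated them. Storing the draws makes every path replayable, which the
#' Girsanov weights and the Bismut-Elworthy-Li stochastic integrals rely on
#' (they must integrate against the *same* Brownian increments that moved the
#' path).
#'
#' Backward batches are stored in increasing-time order: `states[, n, ]` sits
#' at grid node `n`, and `noises[, n, ]` is the draw attached to the interval
#' between nodes `n` and `n + 1`, in both directions.
#'
#' @name trajectory_batch
#' @keywords internal
NULL

new_batch <- function(states, noises, grid, direction, kind) {
  structure(list(states = states, noises = noises, grid = grid,
                 direction = direction, kind = kind),
            class = "trajectory_batch")
}

#' @export
print.trajectory_batch <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<trajectory_batch %s %s: M=%d, %d nodes, state dim %d>\n",
              x$direction, x$kind, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
as.data.frame.trajectory_batch <- function(x, ...) {
  as.data.frame(tidy.trajectory_batch(x))
}

#' Tidy a trajectory batch into long form
#'
#' One row per (path, node, state component). Intended for small batches
#' (plotting, export); large batches are better kept as arrays.
#'
#' @param x A `trajectory_batch`.
#' @param ... Unused.
#' @method tidy trajectory_batch
#' @export
tidy.trajectory_batch <- function(x, ...) {
  d <- dim(x$states)
  comp <- if (x$kind == "underdamped") {
    dd <- d[3] / 2
    c(paste0("q", seq_len(dd)), paste0("p", seq_len(dd)))
  } else paste0("q", seq_len(d[3]))
  tibble::tibble(
    path = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep(x$grid$nodes, each = d[1]), times = d[3]),
    component = rep(comp, each = d[1] * d[2]),
    value = as.numeric(x$states))
}

# Resolve the noises argument: NULL -> fresh draws, "zero" -> test hook,
# array -> user-supplied (replays).
resolve_noises <- function(noises, rng, M, n, d) {
  if (is.null(noises)) {
    abort_if(is.null(rng), "either `rng` or explicit `noises` is required.")
    noise_array(rng, M, n, d)
  } else if (identical(noises, "zero")) {
    array(0, dim = c(M, n, d))
  } else {
    abort_if(!identical(dim(noises), c(M, n, d)) &&
               !identical(dim(noises), as.integer(c(M, n, d))),
             "`noises` has wrong dimensions.")
    noises
  }
}

anchor_matrix <- function(x, M, d) {
  if (is.matrix(x)) {
    abort_if(ncol(x) != d || nrow(x) != M, "anchor batch has wrong shape.")
    x
  } else {
    abort_if(length(x) != d, "anchor must be a d-vector or M x d matrix.")
    matrix(rep(as.numeric(x), each = M), nrow = M)
  }
}

#' Backward auxiliary diffusion for the overdamped solver
#'
#' Simulates the driftless backward process `d q = sqrt(2 mu / beta) dw`
#' anchored at `q_anchor` at the final grid node and integrated down to the
#' first node: `q_{n-1} = q_n - sqrt(2 mu dt_n / beta) eps_n` with i.i.d.
#' standard-normal `eps_n`. These are the auxiliary paths over which the
#' Girsanov-reweighted Fokker-Planck average is taken.
#'
#' @param q_anchor Anchor position: a d-vector (shared by all paths) or an
#'   `M x d` matrix.
#' @param grid A [time_grid()].
#' @param model An [overdamped_model()].
#' @param M Number of paths.
#' @param rng An [rng_stream()] (ignored when `noises` is given).
#' @param noises Optional explicit draws (`M x N x d` array) or `"zero"`.
#' @return A `trajectory_batch` with `direction = "backward"`.
#' @export
simulate_overdamped_backward <- function(q_anchor, grid, model, M, rng = NULL,
                                         noises = NULL) {
  abort_if(!inherits(model, "overdamped_model"), "need an overdamped model.")
  abort_if(M < 1, "`M` must be >= 1.")
  d <- model$d; N <- grid_n(grid)
  eps <- resolve_noises(noises, rng, M, N, d)
  states <- array(0, dim = c(M, N + 1, d))
  states[, N + 1, ] <- anchor_matrix(q_anchor, M, d)
  sc0 <- sqrt(2 * model$mu / model$beta)
  for (n in N:1) {
    states[, n, ] <- states[, n + 1, ] - sqrt(grid$dt[n]) * (eps[, n, ] * sc0)
  }
  new_batch(states, eps, grid, "backward", "overdamped")
}

#' Forward overdamped dynamics
#'
#' Euler-Maruyama integration of
#' `dq = -mu (grad U_t)(q) dt + sqrt(2 mu / beta) dw` from `q_initial` at the
#' first grid node.
#'
#' @param q_initial Initial position (d-vector or `M x d` matrix).
#' @inheritParams simulate_overdamped_backward
#' @return A `trajectory_batch` with `direction = "forward"`.
#' @export
simulate_overdamped_forward <- function(q_initial, grid, model, M, rng = NULL,
                                        noises = NULL) {
  abort_if(!inherits(model, "overdamped_model"), "need an overdamped model.")
  abort_if(M < 1, "`M` must be >= 1.")
  d <- model$d; N <- grid_n(grid)
  eps <- resolve_noises(noises, rng, M, N, d)
  states <- array(0, dim = c(M, N + 1, d))
  states[, 1, ] <- anchor_matrix(q_initial, M, d)
  sc0 <- sqrt(2 * model$mu / model$beta)
  for (n in seq_len(N)) {
    qn <- matrix(states[, n, ], nrow = M)
    g <- pot_grad(model$potential, grid$nodes[n], qn)
    states[, n + 1, ] <- qn - (model$mu * g) * grid$dt[n] +
      sqrt(grid$dt[n]) * (eps[, n, ] * sc0)
  }
  new_batch(states, eps, grid, "forward", "overdamped")
}

#' Backward phase-space diffusion (time-reversal-invariant measure)
#'
#' Integrates, backward from an anchor at the final node, the process whose
#' forward version has symplectic drift but no friction:
#' `q_{n-1} = q_n - (p_n / m) dt_n`,
#' `p_{n-1} = p_n + (grad U_{t_n})(q_n) dt_n - sqrt(2 m dt_n / (tau beta)) eps_n`.
#' The Girsanov factor of [log_weight_underdamped()] converts averages over
#' these paths into solutions of the underdamped Fokker-Planck equation.
#'
#' @param x_anchor Anchor phase point `c(q, p)` (2d-vector or `M x 2d` matrix).
#' @inheritParams simulate_overdamped_backward
#' @param model An [underdamped_model()].
#' @export
simulate_underdamped_backward <- function(x_anchor, grid, model, M, rng = NULL,
                                          noises = NULL) {
  abort_if(!inherits(model, "underdamped_model"), "need an underdamped model.")
  abort_if(M < 1, "`M` must be >= 1.")
  d <- model$d; N <- grid_n(grid)
  eps <- resolve_noises(noises, rng, M, N, d)
  states <- array(0, dim = c(M, N + 1, 2 * d))
  states[, N + 1, ] <- anchor_matrix(x_anchor, M, 2 * d)
  qi <- seq_len(d); pi_ <- d + seq_len(d)
  for (n in N:1) {
    qn <- matrix(states[, n + 1, qi], nrow = M)
    pn <- matrix(states[, n + 1, pi_], nrow = M)
    g <- pot_grad(model$potential, grid$nodes[n + 1], qn)
    sc <- sqrt(2 * model$m * grid$dt[n] / (model$tau * model$beta))
    states[, n, qi] <- qn - pn / model$m * grid$dt[n]
    states[, n, pi_] <- pn + g * grid$dt[n] - sc * eps[, n, ]
  }
  new_batch(states, eps, grid, "backward", "underdamped")
}

#' Forward underdamped dynamics
#'
#' Euler-Maruyama integration of the Langevin-Kramers system
#' `q_{n+1} = q_n + (p_n / m) dt`,
#' `p_{n+1} = p_n - (p_n / tau + (grad U_{t_n})(q_n)) dt
#'            + sqrt(2 m dt / (tau beta)) eps`.
#'
#' @param x_initial Initial phase point `c(q, p)` (2d-vector or `M x 2d`
#'   matrix).
#' @inheritParams simulate_underdamped_backward
#' @export
simulate_underdamped_forward <- function(x_initial, grid, model, M, rng = NULL,
                                         noises = NULL) {
  abort_if(!inherits(model, "underdamped_model"), "need an underdamped model.")
  abort_if(M < 1, "`M` must be >= 1.")
  d <- model$d; N <- grid_n(grid)
  eps <- resolve_noises(noises, rng, M, N, d)
  states <- array(0, dim = c(M, N + 1, 2 * d))
  states[, 1, ] <- anchor_matrix(x_initial, M, 2 * d)
  qi <- seq_len(d); pi_ <- d + seq_len(d)
  for (n in seq_len(N)) {
    qn <- matrix(states[, n, qi], nrow = M)
    pn <- matrix(states[, n, pi_], nrow = M)
    g <- pot_grad(model$potential, grid$nodes[n], qn)
    sc <- sqrt(2 * model$m * grid$dt[n] / (model$tau * model$beta))
    states[, n + 1, qi] <- qn + pn / model$m * grid$dt[n]
    states[, n + 1, pi_] <- pn - (pn / model$tau + g) * grid$dt[n] +
      sc * eps[, n, ]
  }
  new_batch(states, eps, grid, "forward", "underdamped")
}

#' Re-integrate a batch from its stored noises
#'
#' Replays the deterministic Euler-Maruyama map on the stored draws; the
#' result must reproduce `batch$states` exactly. Used to assert the replay
#' invariant and to rebuild states after serialization of noises only.
#'
#' @param batch A `trajectory_batch`.
#' @param model The model that generated it.
#' @export
replay_batch <- function(batch, model) {
  M <- dim(batch$states)[1]
  n_nodes <- dim(batch$states)[2]
  if (batch$kind == "overdamped" && batch$direction == "backward") {
    simulate_overdamped_backward(matrix(batch$states[, n_nodes, ], nrow = M),
                                 batch$grid, model, M, noises = batch$noises)
  } else if (batch$kind == "overdamped") {
    simulate_overdamped_forward(matrix(batch$states[, 1, ], nrow = M),
                                batch$grid, model, M, noises = batch$noises)
  } else if (batch$direction == "backward") {
    simulate_underdamped_backward(matrix(batch$states[, n_nodes, ], nrow = M),
                                  batch$grid, model, M, noises = batch$noises)
  } else {
    simulate_underdamped_forward(matrix(batch$states[, 1, ], nrow = M),
                                 batch$grid, model, M, noises = batch$noises)
  }
}
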