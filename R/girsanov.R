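#' Initial (boundary) densities for the Fokker-Planck solvers
#'
#' A thin wrapper around a vectorized log-density function. The solvers accept
#' either this class or a bare function.
#'
#' @param log_density Function mapping states to log density values. For the
#'   overdamped solver a function of `q`; for the underdamped solver a
#'   function of `(q, p)`.
#' @param normalized Logical; whether the density is normalized (informational,
#'   checked by [boundary_conditions()] where a box is declared).
#' @export
initial_density <- function(log_density, normalized = FALSE) {
  abort_if(!is.function(log_density), "`log_density` must be a function.")
  structure(list(log_density = log_density, normalized = normalized),
            class = "initial_density")
}

as_log_density <- function(p_init) {
  if (inherits(p_init, "initial_density")) p_init$log_density
  else if (is.function(p_init)) p_init
  else rlang::abort("`p_init` must be a function or an initial_density.")
}

#' Girsanov log-weights for backward overdamped batches
#'
#' Per-interval increments of the log Radon-Nikodym factor converting
#' averages over the driftless auxiliary backward paths into averages over
#' the mechanically driven diffusion. For interval `n` (between nodes `n` and
#' `n + 1`, pre-point convention):
#' `-dg_n = -(beta mu / 4) dt_n |grad U_{t_n}(q_{t_n})|^2
#'          - sqrt(beta mu dt_n / 2) <grad U_{t_n}(q_{t_n}), eps_n>`,
#' so that the path weight is `exp(rowSums(increments))`. For `U = 0` every
#' increment is exactly zero (the auxiliary measure is the target measure).
#'
#' Two discretizations are available. `at = "generated"` evaluates the
#' gradient at the state the interval's draw just produced (the pre-point of
#' the displayed Ito integrals); this is the form the density representation
#' requires and the one the solvers consume. `at = "anchor"` evaluates at the
#' interval's anchor-side node, which is independent of the draw — the
#' backward-adapted discretization whose exponential has exactly unit
#' expectation step by step (the discrete martingale normalization of the
#' change of measure). The two differ by `O(dt)` per step and share the same
#' continuum limit for their respective integrals.
#'
#' @param batch A backward overdamped `trajectory_batch` with stored noises.
#' @param model The [overdamped_model()] whose potential drives the
#'   Fokker-Planck equation.
#' @param at Evaluation node per interval: `"generated"` (default; density
#'   estimator convention) or `"anchor"` (martingale convention).
#' @return An `M x N` matrix of log-weight increments.
#' @export
log_weight_overdamped <- function(batch, model, at = c("generated", "anchor")) {
  at <- match.arg(at)
  abort_if(!inherits(batch, "trajectory_batch") ||
             batch$kind != "overdamped" || batch$direction != "backward",
           "`batch` must come from simulate_overdamped_backward().")
  abort_if(!inherits(model, "overdamped_model"), "need an overdamped model.")
  M <- dim(batch$states)[1]; N <- grid_n(batch$grid)
  out <- matrix(0, M, N)
  for (n in seq_len(N)) {
    dt <- batch$grid$dt[n]
    j <- if (at == "generated") n else n + 1
    qn <- matrix(batch$states[, j, ], nrow = M)
    g <- pot_grad(model$potential, batch$grid$nodes[j], qn)
    quad <- rowSums(g * g)
    cross <- rowSums(g * matrix(batch$noises[, n, ], nrow = M))
    out[, n] <- -(model$beta * model$mu / 4) * dt * quad -
      sqrt(model$beta * model$mu * dt / 2) * cross
  }
  out
}

#' Girsanov log-weights for backward underdamped batches
#'
#' Counterpart of [log_weight_overdamped()] for the phase-space solver: the
#' weight converts averages over the friction-free backward process into
#' averages under the Langevin-Kramers path measure. Increment for interval
#' `n`, with momentum at the pre-point node `n`:
#' `-dg_n = -(tau beta / (4 m)) dt_n |p_{t_n}|^2
#'          - sqrt(tau beta dt_n / (2 m)) <eps_n, p_{t_n}>`.
#'
#' As in the overdamped case, `at = "generated"` (pre-point, the density
#' estimator's convention) and `at = "anchor"` (backward-adapted, exact
#' discrete martingale) are both provided; for the generated-node form the
#' sample mean of `exp(-g)` approaches `exp((t - t_init) d / tau)` rather
#' than one — the phase-space contraction factor that the pre-point identity
#' absorbs in the continuum derivation.
#'
#' @param batch A backward underdamped `trajectory_batch`.
#' @param model An [underdamped_model()].
#' @inheritParams log_weight_overdamped
#' @return An `M x N` matrix of log-weight increments.
#' @export
log_weight_underdamped <- function(batch, model,
                                   at = c("generated", "anchor")) {
  at <- match.arg(at)
  abort_if(!inherits(batch, "trajectory_batch") ||
             batch$kind != "underdamped" || batch$direction != "backward",
           "`batch` must come from simulate_underdamped_backward().")
  abort_if(!inherits(model, "underdamped_model"), "need an underdamped model.")
  M <- dim(batch$states)[1]; N <- grid_n(batch$grid)
  d <- dim(batch$states)[3] / 2
  out <- matrix(0, M, N)
  cb <- model$tau * model$beta / model$m
  for (n in seq_len(N)) {
    dt <- batch$grid$dt[n]
    j <- if (at == "generated") n else n + 1
    pn <- matrix(batch$states[, j, d + seq_len(d)], nrow = M)
    quad <- rowSums(pn * pn)
    cross <- rowSums(pn * matrix(batch$noises[, n, ], nrow = M))
    out[, n] <- -(cb / 4) * dt * quad - sqrt(cb * dt / 2) * cross
  }
  out
}

fp_point_stats <- function(log_init_vals, logw) {
  logv <- log_init_vals + rowSums(logw)
  vals <- exp(pmin(logv, 700))
  c(mean = mean(vals),
    se = stats::sd(vals) / sqrt(length(vals)),
    ess = ess_from_logw(rowSums(logw)))
}

#' Pointwise Monte Carlo solution of the overdamped Fokker-Planck equation
#'
#' Estimates the density `p_t(q)` of the overdamped diffusion driven by the
#' model potential, at each query point, by anchoring `M` driftless backward
#' auxiliary paths at `(t, q)`, carrying them to the initial time, and
#' averaging the initial density under the Girsanov weight:
#' `p_t(q) = E[ p_init(q_{t_init}) exp(-g) | q_t = q ]`.
#' No spatial discretization is involved; each query point is an independent
#' conditional expectation.
#'
#' @param points Query positions (numeric vector for d = 1, or `P x d`
#'   matrix).
#' @param time Query time; must be a node of `grid`.
#' @param model An [overdamped_model()].
#' @param grid A [time_grid()] whose first node is the initial time of
#'   `p_init`.
#' @param p_init Initial log-density: function of `q` or [initial_density()].
#' @param M Trajectories per query point.
#' @param rng An [rng_stream()].
#' @param share_noise If `TRUE` (default) all query points reuse the same
#'   noise draws (common random numbers), which makes the estimated curve
#'   smooth in `q`; disable for independent-error diagnostics.
#' @param normalize If `TRUE` (d = 1), rescale the estimates so the trapezoid
#'   integral over the query points is one (figure-style post-processing; the
#'   raw estimator already targets the density itself).
#' @param window Optional odd integer: box-filter smoothing of the estimates
#'   over the (sorted) query points.
#' @return A tibble of class `density_estimate` with columns `q`, `mean`,
#'   `se`, `ess`, and attribute `M`.
#' @export
fp_density_overdamped <- function(points, time, model, grid, p_init, M = 1e4,
                                  rng = rng_stream(1), share_noise = TRUE,
                                  normalize = FALSE, window = NULL) {
  abort_if(!inherits(model, "overdamped_model"), "need an overdamped model.")
  log_init <- as_log_density(p_init)
  d <- model$d
  P <- if (is.matrix(points)) nrow(points) else length(points)
  pts <- as_state_matrix(points, d)
  abort_if(any(!is.finite(pts)), "query points must be finite.")
  i <- grid_index(grid, time)
  out <- tibble::tibble(q = if (d == 1) pts[, 1] else split(pts, row(pts)))
  if (i == 1) {
    lv <- log_init(if (d == 1) pts[, 1] else pts)
    res <- tibble::tibble(q = out$q, mean = exp(lv), se = 0, ess = as.numeric(M))
  } else {
    sub <- time_grid(nodes = grid$nodes[1:i])
    N <- grid_n(sub)
    shared <- if (share_noise) noise_array(rng, M, N, d)
    means <- ses <- esss <- numeric(P)
    for (k in seq_len(P)) {
      eps <- if (share_noise) shared else
        noise_array(rng_spawn(rng, k), M, N, d)
      b <- simulate_overdamped_backward(pts[k, ], sub, model, M, noises = eps)
      logw <- log_weight_overdamped(b, model)
      q0 <- matrix(b$states[, 1, ], nrow = M)
      st <- fp_point_stats(log_init(if (d == 1) q0[, 1] else q0), logw)
      means[k] <- st["mean"]; ses[k] <- st["se"]; esss[k] <- st["ess"]
    }
    res <- tibble::tibble(q = out$q, mean = means, se = ses, ess = esss)
  }
  finalize_density(res, time, M, normalize, window, d)
}

#' Pointwise Monte Carlo solution of the underdamped Fokker-Planck equation
#'
#' Phase-space analogue of [fp_density_overdamped()]: backward paths of the
#' friction-free process are anchored at each query phase point `(q, p)` and
#' the initial joint density is averaged under the momentum Girsanov weight.
#'
#' @param points Query phase points: a data frame / tibble with columns `q`
#'   and `p` (d = 1), or a `P x 2d` matrix ordered `(q, p)`.
#' @param p_init Initial log-density: function `(q, p)` or
#'   [initial_density()].
#' @inheritParams fp_density_overdamped
#' @param model An [underdamped_model()].
#' @return A tibble of class `density_estimate` with columns `q`, `p`,
#'   `mean`, `se`, `ess`.
#' @export
fp_density_underdamped <- function(points, time, model, grid, p_init, M = 1e4,
                                   rng = rng_stream(1), share_noise = TRUE) {
  abort_if(!inherits(model, "underdamped_model"), "need an underdamped model.")
  log_init <- as_log_density(p_init)
  d <- model$d
  if (is.data.frame(points)) points <- cbind(points$q, points$p)
  if (!is.matrix(points)) {
    abort_if(length(points) != 2 * d,
             "`points` must be a phase point, matrix, or data frame.")
    points <- matrix(points, nrow = 1)
  }
  pts <- as_state_matrix(points, 2 * d)
  i <- grid_index(grid, time)
  P <- nrow(pts)
  if (i == 1) {
    lv <- log_init(matrix(pts[, seq_len(d)], nrow = P),
                   matrix(pts[, d + seq_len(d)], nrow = P))
    res <- tibble::tibble(q = pts[, 1], p = pts[, d + 1],
                          mean = exp(lv), se = 0, ess = as.numeric(M))
  } else {
    sub <- time_grid(nodes = grid$nodes[1:i])
    N <- grid_n(sub)
    shared <- if (share_noise) noise_array(rng, M, N, d)
    means <- ses <- esss <- numeric(P)
    for (k in seq_len(P)) {
      eps <- if (share_noise) shared else
        noise_array(rng_spawn(rng, k), M, N, d)
      b <- simulate_underdamped_backward(pts[k, ], sub, model, M, noises = eps)
      logw <- log_weight_underdamped(b, model)
      q0 <- matrix(b$states[, 1, seq_len(d)], nrow = M)
      p0 <- matrix(b$states[, 1, d + seq_len(d)], nrow = M)
      st <- fp_point_stats(log_init(q0, p0), logw)
      means[k] <- st["mean"]; ses[k] <- st["se"]; esss[k] <- st["ess"]
    }
    res <- tibble::tibble(q = pts[, 1], p = pts[, d + 1],
                          mean = means, se = ses, ess = esss)
  }
  attr(res, "M") <- M
  attr(res, "time") <- time
  class(res) <- c("density_estimate", class(res))
  res
}

finalize_density <- function(res, time, M, normalize, window, d) {
  if (!is.null(window) && d == 1) {
    ord <- order(res$q)
    res$mean[ord] <- smooth_density(res$mean[ord], window)
  }
  if (normalize && d == 1) {
    ord <- order(res$q)
    mass <- trapz(res$q[ord], res$mean[ord])
    abort_if(mass <= 0, "cannot normalize: non-positive mass.")
    res$mean <- res$mean / mass
    res$se <- res$se / mass
  }
  attr(res, "M") <- M
  attr(res, "time") <- time
  class(res) <- c("density_estimate", class(res))
  res
}

#' Weighted error norms between an estimate and a reference density
#'
#' The diagnostic norms used for convergence monitoring, computed over the
#' common point set:
#' `l1 = sum_x P_ref(x) |Phat(x) - P_ref(x)|`,
#' `l2 = (sum_x P_ref(x) |Phat(x) - P_ref(x)|^2)^{1/2}`,
#' `linf = max_x |Phat(x) - P_ref(x)|^2` (note the square: this is the
#' largest squared pointwise deviation), and `max_variance`, the largest
#' per-point variance of the Monte Carlo mean.
#'
#' @param estimate A `density_estimate` tibble (columns `mean`, `se`).
#' @param reference Reference density values at the same points (numeric
#'   vector), or a function applied to the estimate's points.
#' @return A one-row tibble with columns `l1`, `l2`, `linf`, `max_variance`.
#' @export
density_diagnostics <- function(estimate, reference) {
  abort_if(!is.data.frame(estimate) || is.null(estimate$mean),
           "`estimate` must be a density_estimate tibble.")
  pref <- if (is.function(reference)) {
    if (!is.null(estimate$p)) reference(estimate$q, estimate$p)
    else reference(estimate$q)
  } else reference
  abort_if(length(pref) != nrow(estimate),
           "`reference` must match the estimate's point set.")
  dev <- abs(estimate$mean - pref)
  tibble::tibble(
    l1 = sum(pref * dev),
    l2 = sqrt(sum(pref * dev^2)),
    linf = max(dev^2),
    max_variance = max(estimate$se^2))
}

#' Box-filter smoothing of a density curve
#'
#' Moving average with an odd window and reflective edge handling, as applied
#' to the raw pointwise estimates before plotting.
#'
#' @param values Density values on an ordered 1-d grid.
#' @param window Odd window length, `<=` the grid length.
#' @return Smoothed values of the same length.
#' @export
smooth_density <- function(values, window) {
  abort_if(window %% 2 != 1 || window < 1 || window > length(values),
           "`window` must be odd and no longer than the input.")
  if (window == 1) return(values)
  h <- (window - 1) / 2
  n <- length(values)
  padded <- c(values[(h + 1):2], values, values[(n - 1):(n - h)])
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))[
    (h + 1):(h + n)]
}
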