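#' Variational fields for the degenerate (underdamped) BEL formula
#'
#' In the Langevin-Kramers system the noise enters only the momentum, so the
#' volatility matrix cannot be inverted and the non-degenerate gradient
#' estimator does not apply. Instead a vector field `h_u` is constructed
#' explicitly so that the perturbed flow ends with a pure momentum (or
#' position) displacement. The construction starts from a free function
#' `ell_u` on the horizon `[t, s]` and derives
#' `g_u = (1/m) int_t^u ell`, and
#' `h_u = -ell'_u - ell_u / tau - Hess U_u(q_u) g_u`
#' (the Hessian term is evaluated along each sampled path).
#'
#' Admissible choices for a momentum-direction gradient require
#' `ell_t = v`, `ell_s = 0` and `g_s = 0`; the estimator's value does not
#' depend on which admissible `ell` is used (only its variance does). Two
#' families are provided, plus one for position-direction gradients:
#' \describe{
#'   \item{`cubic`}{`ell_u = v (s-u)(s + 2t - 3u) / (s-t)^2`, the smooth
#'     polynomial family.}
#'   \item{`tent`}{piecewise-linear `ell` through `(t, v)`,
#'     `((t+s)/2, -v/2)`, `(s, 0)` — same endpoint and zero-integral
#'     constraints, different shape.}
#'   \item{`qbump`}{`ell_u = -6 m v (u-t)(s-u) / (s-t)^3` with
#'     `ell_t = ell_s = 0` and `g_s = -v`, which turns the terminal
#'     displacement into a position direction (experimental; validated
#'     against the finite-difference oracle).}
#' }
#'
#' @param t,tf Horizon endpoints, `t < tf`.
#' @param model An [underdamped_model()] (supplies `m`, `tau`).
#' @param v Direction vector (length d); normalized internally.
#' @param type Field family (see above).
#' @return An object of class `variational_field` with vectorized closures
#'   `ell(u)`, `elldot(u)`, `g(u)` (each `length(u) x d`), and the horizon.
#'   `h_u` is assembled on the fly by the estimator since it depends on the
#'   sampled path through the Hessian.
#' @export
make_variational_field <- function(t, tf, model, v = 1,
                                   type = c("cubic", "tent", "qbump")) {
  type <- match.arg(type)
  abort_if(t >= tf, "`t` must be strictly before `tf`.")
  d <- model$d
  abort_if(length(v) != d, "`v` must have the model dimension.")
  nv <- sqrt(sum(v^2))
  abort_if(nv == 0, "`v` must be non-zero.")
  v <- v / nv
  m <- model$m
  TT <- tf - t
  outer_v <- function(s) outer(s, v)  # length(u) x d
  fns <- switch(type,
    cubic = list(
      ell = function(u) outer_v((tf - u) * (tf + 2 * t - 3 * u) / TT^2),
      elldot = function(u) outer_v((6 * u - 4 * tf - 2 * t) / TT^2),
      g = function(u) outer_v((tf - u)^2 * (u - t) / (m * TT^2)),
      direction = "p"),
    tent = {
      tm <- (t + tf) / 2
      list(
        ell = function(u) outer_v(ifelse(u < tm,
          1 - 3 * (u - t) / TT, -0.5 + (u - tm) / TT)),
        elldot = function(u) outer_v(ifelse(u < tm, -3 / TT, 1 / TT)),
        g = function(u) outer_v(ifelse(u < tm,
          ((u - t) - 1.5 * (u - t)^2 / TT) / m,
          (TT / 8 - 0.5 * (u - tm) + 0.5 * (u - tm)^2 / TT) / m)),
        direction = "p")
    },
    qbump = list(
      ell = function(u) outer_v(-6 * m * (u - t) * (tf - u) / TT^3),
      elldot = function(u) outer_v(-6 * m * (tf + t - 2 * u) / TT^3),
      g = function(u) outer_v(-(u - t)^2 * (3 * tf - t - 2 * u) / TT^3),
      direction = "q"))
  structure(c(fns, list(t = t, tf = tf, v = v, tau = model$tau, m = m,
                        type = type)),
            class = "variational_field")
}

#' @export
print.variational_field <- function(x, ...) {
  cat(sprintf("<variational_field %s on [%g, %g], %s-direction>\n",
              x$type, x$t, x$tf, x$direction))
  invisible(x)
}

# h_u for a field on horizon [t, s], excluding the Hessian term:
# h0_u = -ell'_u - ell_u / tau; the full h is h0_u - Hess(q_u) g_u.
field_h0 <- function(field, u) -field$elldot(u) - field$ell(u) / field$tau

#' Bismut-Elworthy-Li gradient for the underdamped (degenerate) value function
#'
#' Estimates the momentum-direction derivative `<v, grad_p V_t(x)>` (or the
#' position-direction one, with `type = "qbump"`) of the phase-space Dynkin
#' value `V_t(x) = E[phi(x_tf) + int F]` along forward Langevin-Kramers
#' paths. The stochastic-integral weight uses the explicitly constructed
#' variational field: for the terminal term the field is built on the full
#' horizon `[t, tf]`; inside the running-cost term the field is rebuilt on
#' each sub-horizon `[t, s]`, since the value-gradient identity underlying
#' the weight holds horizon by horizon.
#'
#' The default running cost is the underdamped Kullback-Leibler bridge cost
#' `(beta tau / (4 m)) |grad U|^2`.
#'
#' @param x Starting phase point(s): `c(q, p)`, a `P x 2d` matrix, or a data
#'   frame with columns `q` and `p` (d = 1); one estimate per point.
#' @param time Start time (a grid node strictly before the final node).
#' @param model An [underdamped_model()] (the potential needs a Hessian when
#'   it is not identically zero).
#' @param grid A [time_grid()] ending at the terminal time.
#' @param terminal Terminal cost `phi(q, p)` (function of two vectors).
#' @param running_cost `"bridge"` (default), `"none"`, or `(t, q, p)`
#'   function.
#' @param M Number of sampled paths.
#' @param rng An [rng_stream()].
#' @param type Variational-field family, see [make_variational_field()].
#' @param v Direction vector (length d).
#' @param share_noise Reuse one set of draws across query points (common
#'   random numbers; default `TRUE`).
#' @param noises Optional explicit draws (`M x N x d`, shared by all points).
#' @return A tibble with one row per query point: `q`, `p`, `estimate`, `se`,
#'   `M`.
#' @export
bel_gradient_underdamped <- function(x, time, model, grid, terminal,
                                     running_cost = "bridge", M = 1e4,
                                     rng = rng_stream(1),
                                     type = c("cubic", "tent", "qbump"),
                                     v = 1, share_noise = TRUE,
                                     noises = NULL) {
  type <- match.arg(type)
  abort_if(!inherits(model, "underdamped_model"), "need an underdamped model.")
  i <- grid_index(grid, time)
  nn <- length(grid$nodes)
  abort_if(i >= nn, "`time` must be strictly before the final grid node.")
  d <- model$d
  if (is.data.frame(x)) x <- cbind(x$q, x$p)
  if (!is.matrix(x)) {
    abort_if(length(x) != 2 * d, "`x` must be a phase point c(q, p).")
    x <- matrix(x, nrow = 1)
  }
  pts <- as_state_matrix(x, 2 * d)
  P <- nrow(pts)
  sub <- time_grid(nodes = grid$nodes[i:nn])
  N <- grid_n(sub)
  M_in <- M
  eps <- if (!is.null(noises)) rep_noise(noises, P)
         else if (share_noise) rep_noise(noise_array(rng, M, N, d), P)
         else noise_array(rng, P * M, N, d)
  anchors <- pts[rep(seq_len(P), each = M), , drop = FALSE]
  M <- P * M
  batch <- simulate_underdamped_forward(anchors, sub, model, M, noises = eps)
  inv_a <- sqrt(model$tau * model$beta / (2 * model$m))
  zero_pot <- is.null(model$potential$hessian)
  # Hessian along paths at each node (pre-point), if the potential has one.
  hess_node <- function(n) {
    Q <- matrix(batch$states[, n, seq_len(d)], nrow = M)
    pot_hess(model$potential, sub$nodes[n], Q)
  }
  # Weight increment at interval n for a field on horizon [t, s]:
  # sqrt(dt_n) * <eps_n, A^-1 (h0(t_n) - Hess(q_n) g(t_n))>.
  w_inc <- function(field, n, H) {
    h <- field_h0(field, sub$nodes[n])  # 1 x d
    hv <- matrix(rep(h, each = M), nrow = M)
    gv <- field$g(sub$nodes[n])
    if (!is.null(H)) {
      for (a in seq_len(d)) for (b in seq_len(d)) {
        hv[, a] <- hv[, a] - H[, a, b] * gv[1, b]
      }
    }
    E <- matrix(batch$noises[, n, ], nrow = M)
    sqrt(sub$dt[n]) * inv_a * rowSums(E * hv)
  }
  prob <- underdamped_problem(model, terminal, running_cost)
  H_nodes <- if (!zero_pot) lapply(seq_len(N), hess_node)
  # Terminal term: field on the full horizon.
  f_full <- make_variational_field(sub$nodes[1], sub$nodes[N + 1], model,
                                   v = v, type = type)
  W <- numeric(M)
  for (n in seq_len(N)) {
    W <- W + w_inc(f_full, n, if (!zero_pot) H_nodes[[n]])
  }
  phi_vals <- prob$terminal(matrix(batch$states[, N + 1, ], nrow = M))
  contrib <- phi_vals * W
  # Running-cost term: field rebuilt on each sub-horizon [t, t_n].
  if (!is.null(prob$running_cost) && N >= 2) {
    for (n in 2:N) {
      f_sub <- make_variational_field(sub$nodes[1], sub$nodes[n], model,
                                      v = v, type = type)
      Wn <- numeric(M)
      for (j in seq_len(n - 1)) {
        Wn <- Wn + w_inc(f_sub, j, if (!zero_pot) H_nodes[[j]])
      }
      Fn <- prob$running_cost(sub$nodes[n],
                              matrix(batch$states[, n, ], nrow = M))
      contrib <- contrib + Fn * Wn * sub$dt[n]
    }
  }
  st <- bel_group_stats(contrib, P, M_in)
  tibble::tibble(q = pts[, 1], p = pts[, d + 1],
                 estimate = st$mean, se = st$se, M = M_in)
}
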