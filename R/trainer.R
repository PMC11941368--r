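#' Parametrized drift models for protocol learning
#'
#' The learned control protocol is the mechanical force `grad U_t(q)`,
#' modelled as a parameter-differentiable map `(t, q) -> drift` that can be
#' evaluated at arbitrary inputs without interpolation. Two implementations
#' are provided:
#'
#' * `drift_nn()` — a fully connected feed-forward network
#'   `(t, q) -> 4 -> 10 -> 1` with swish activations (`x * sigmoid(x)`)
#'   after the first and second hidden layers, Glorot-normal initialization
#'   for the hidden weights and Glorot-uniform for the output layer. The
#'   caption-style "input layer of four neurons" is read as a 4-unit first
#'   hidden layer fed by the two inputs `(t, q)`. Gradients with respect to
#'   the parameters (backpropagation) and to `q` (forward-mode, needed for
#'   the tangent-flow Hessian) are computed analytically.
#' * `drift_poly()` — a tensor polynomial `sum c_ij t^i q^j`, useful as a
#'   dependency-light, exactly-differentiable stand-in in tests.
#'
#' @param widths Hidden-layer widths for `drift_nn`.
#' @param rng An [rng_stream()] for the initialization.
#' @return An object of class `drift_model` (subclass `drift_nn` or
#'   `drift_poly`).
#' @name drift_models
NULL

sigm <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigm(x)
swish_d <- function(x) { s <- sigm(x); s * (1 + x * (1 - s)) }

#' @rdname drift_models
#' @export
drift_nn <- function(widths = c(4, 10), rng = rng_stream(7)) {
  abort_if(length(widths) != 2, "`drift_nn` uses exactly two hidden layers.")
  n1 <- widths[1]; n2 <- widths[2]
  pars <- with_rng(rng, {
    glorot_n <- function(fan_in, fan_out)
      matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
             nrow = fan_out)
    glorot_u <- function(fan_in, fan_out) {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(runif(fan_in * fan_out, -lim, lim), nrow = fan_out)
    }
    list(W1 = glorot_n(2, n1), b1 = numeric(n1),
         W2 = glorot_n(n1, n2), b2 = numeric(n2),
         W3 = glorot_u(n2, 1), b3 = 0)
  })
  structure(list(pars = pars, opt_state = NULL),
            class = c("drift_nn", "drift_model"))
}

#' @rdname drift_models
#' @param degree_t,degree_q Polynomial degrees in `t` and `q`.
#' @export
drift_poly <- function(degree_t = 1, degree_q = 3) {
  structure(list(pars = list(C = matrix(0, degree_t + 1, degree_q + 1)),
                 opt_state = NULL),
            class = c("drift_poly", "drift_model"))
}

#' Evaluate a drift model
#'
#' @param drift A drift model.
#' @param t Time(s) — scalar or vector recycled against `q`.
#' @param q Position(s).
#' @return Drift values, same length as `q`.
#' @export
drift_eval <- function(drift, t, q) UseMethod("drift_eval")

#' Spatial derivative of a drift model
#'
#' `d(drift)/dq`, the curvature of the learned potential; consumed by the
#' tangent-flow cocycle.
#'
#' @inheritParams drift_eval
#' @export
drift_eval_dq <- function(drift, t, q) UseMethod("drift_eval_dq")

nn_forward <- function(p, t, q) {
  X <- cbind(rep_len(t, length(q)), q)
  Z1 <- X %*% t(p$W1) + rep(p$b1, each = nrow(X))
  A1 <- swish(Z1)
  Z2 <- A1 %*% t(p$W2) + rep(p$b2, each = nrow(X))
  A2 <- swish(Z2)
  out <- A2 %*% t(p$W3) + p$b3
  list(X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, out = as.numeric(out))
}

#' @export
drift_eval.drift_nn <- function(drift, t, q) nn_forward(drift$pars, t, q)$out

#' @export
drift_eval_dq.drift_nn <- function(drift, t, q) {
  p <- drift$pars
  f <- nn_forward(p, t, q)
  # forward-mode derivative with respect to the q input
  dZ1 <- matrix(p$W1[, 2], nrow = length(q), ncol = nrow(p$W1), byrow = TRUE)
  dA1 <- swish_d(f$Z1) * dZ1
  dZ2 <- dA1 %*% t(p$W2)
  dA2 <- swish_d(f$Z2) * dZ2
  as.numeric(dA2 %*% t(p$W3))
}

# Backpropagated parameter gradient of mean((out - target)^2) / 2.
nn_grad <- function(p, t, q, target) {
  f <- nn_forward(p, t, q)
  n <- length(q)
  d_out <- (f$out - target) / n           # n x 1
  gW3 <- matrix(d_out, nrow = 1) %*% f$A2
  gb3 <- sum(d_out)
  dA2 <- d_out %*% p$W3                   # n x n2
  dZ2 <- dA2 * swish_d(f$Z2)
  gW2 <- t(dZ2) %*% f$A1
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% p$W2
  dZ1 <- dA1 * swish_d(f$Z1)
  gW1 <- t(dZ1) %*% f$X
  gb1 <- colSums(dZ1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       loss = mean((f$out - target)^2))
}

poly_design <- function(C, t, q) {
  t <- rep_len(t, length(q))
  Ti <- outer(t, 0:(nrow(C) - 1), "^")
  Qj <- outer(q, 0:(ncol(C) - 1), "^")
  list(Ti = Ti, Qj = Qj)
}

#' @export
drift_eval.drift_poly <- function(drift, t, q) {
  C <- drift$pars$C
  d <- poly_design(C, t, q)
  rowSums((d$Ti %*% C) * d$Qj)
}

#' @export
drift_eval_dq.drift_poly <- function(drift, t, q) {
  C <- drift$pars$C
  if (ncol(C) == 1) return(rep(0, length(q)))
  Cq <- C[, -1, drop = FALSE] %*% diag(seq_len(ncol(C) - 1),
                                       nrow = ncol(C) - 1)
  d <- poly_design(Cq, t, q)
  rowSums((d$Ti %*% Cq) * d$Qj)
}

poly_grad <- function(C, t, q, target) {
  d <- poly_design(C, t, q)
  resid <- rowSums((d$Ti %*% C) * d$Qj) - target
  g <- t(d$Ti) %*% (d$Qj * (resid / length(q)))
  list(grads = list(C = g), loss = mean(resid^2))
}

#' View a drift model as a (value-free) potential
#'
#' Wraps the drift as the gradient accessor of a [potential()], with
#' `drift_eval_dq` as its Hessian, so a learned protocol can drive the
#' Fokker-Planck and value-gradient estimators directly.
#'
#' @param drift A drift model.
#' @return A [potential()] (no `value` accessor).
#' @export
drift_potential <- function(drift) {
  force(drift)
  potential(gradient = function(t, q) drift_eval(drift, t, q),
            hessian = function(t, q) drift_eval_dq(drift, t, q),
            d = 1L)
}

# One optimizer step over a named list of parameter arrays.
opt_step <- function(pars, grads, state, rate, optimizer) {
  if (optimizer == "sgd") {
    for (nm in names(grads)) pars[[nm]] <- pars[[nm]] - rate * grads[[nm]]
    return(list(pars = pars, state = state))
  }
  # adam
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (is.null(state)) {
    state <- list(t = 0,
                  m = lapply(grads, function(g) g * 0),
                  v = lapply(grads, function(g) g * 0))
  }
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    pars[[nm]] <- pars[[nm]] - rate * mhat / (sqrt(vhat) + eps)
  }
  list(pars = pars, state = state)
}

#' Fit a drift model to value-gradient targets
#'
#' Runs `steps` full-batch first-order updates minimizing the mean squared
#' mismatch between the drift model and the stationarity targets
#' `(2 / beta) grad V_{t_n}(q_k)` (or any supplied targets). A rate of zero
#' leaves the parameters untouched.
#'
#' @param drift A drift model.
#' @param data A data frame with columns `t`, `q`, `target`.
#' @param rate Learning rate `gamma_2`.
#' @param steps Number of updates.
#' @param optimizer `"sgd"` or `"adam"` (Adam state persists on the model
#'   across calls).
#' @return The updated drift model, with attribute `"loss"` holding the final
#'   mean squared error.
#' @export
fit_drift <- function(drift, data, rate, steps = 100, optimizer = "sgd") {
  abort_if(!all(c("t", "q", "target") %in% names(data)),
           "`data` needs columns t, q, target.")
  abort_if(any(!is.finite(data$target)), "targets must be finite.")
  loss <- NA_real_
  for (s in seq_len(steps)) {
    gr <- if (inherits(drift, "drift_nn")) {
      nn_grad(drift$pars, data$t, data$q, data$target)
    } else {
      poly_grad(drift$pars$C, data$t, data$q, data$target)
    }
    loss <- gr$loss
    abort_if(!is.finite(loss), "non-finite training loss; aborting fit.")
    if (rate > 0) {
      st <- opt_step(drift$pars, gr$grads, drift$opt_state, rate, optimizer)
      drift$pars <- st$pars
      drift$opt_state <- st$state
    }
  }
  attr(drift, "loss") <- loss
  drift
}

#' Polynomial Lagrange multiplier
#'
#' The terminal condition of the value function is the multiplier enforcing
#' the final marginal, `V_tf(q) = lambda(q)`, represented as a polynomial of
#' fixed degree with all coefficients initialized to zero.
#'
#' @param degree Polynomial degree (default 6).
#' @param coef Optional coefficient vector (constant term first).
#' @export
multiplier_poly <- function(degree = 6, coef = NULL) {
  if (is.null(coef)) coef <- numeric(degree + 1)
  abort_if(length(coef) != degree + 1, "`coef` must have degree + 1 entries.")
  structure(list(coef = coef, degree = degree), class = "multiplier_poly")
}

#' Evaluate the multiplier polynomial
#' @param lambda A [multiplier_poly()].
#' @param q Positions.
#' @param derivative If `TRUE`, return `lambda'(q)`.
#' @export
multiplier_eval <- function(lambda, q, derivative = FALSE) {
  cf <- lambda$coef
  if (derivative) {
    if (length(cf) == 1) return(rep(0, length(q)))
    cf <- cf[-1] * seq_len(length(cf) - 1)
  }
  out <- rep(cf[length(cf)], length(q))
  if (length(cf) > 1) for (k in (length(cf) - 1):1) out <- out * q + cf[k]
  out
}

#' Ascent update of the Lagrange multiplier
#'
#' Moves the multiplier toward enforcing the final marginal:
#' the pointwise targets are
#' `lambda_old(q_k) + gamma1 * log(phat_tf(q_k) / P_f(q_k))`
#' and the new coefficients are the ordinary least-squares polynomial fit to
#' those targets over the batch. When the estimated final density already
#' equals the target marginal the update is an exact fixed point. Density
#' ratios are floored at `1e-300` before the logarithm.
#'
#' @param lambda A [multiplier_poly()].
#' @param q Batch points.
#' @param p_hat Estimated final density at `q`.
#' @param p_f Target final density at `q`.
#' @param gamma1 Ascent rate.
#' @return The updated [multiplier_poly()].
#' @export
update_multiplier <- function(lambda, q, p_hat, p_f, gamma1) {
  abort_if(length(q) < lambda$degree + 1,
           "need at least degree + 1 batch points for the fit.")
  target <- multiplier_eval(lambda, q) +
    gamma1 * log(pmax(p_hat, 1e-300) / pmax(p_f, 1e-300))
  X <- outer(q, 0:lambda$degree, "^")
  cf <- qr.coef(qr(X), target)
  cf[is.na(cf)] <- 0
  multiplier_poly(lambda$degree, coef = as.numeric(cf))
}

#' Trainer configuration
#'
#' Collects the knobs of the protocol-learning loop. The default `phases`
#' schedule mirrors the reference four-phase recipe: 20 outer iterations per
#' phase; drift updates per iteration 100, 100, 400, 400; drift rates
#' `gamma2` of 1e-3, 1e-4, 1e-5, 1e-4; multiplier rates `gamma1` of 0.1 then
#' 1e-2; SGD for the first three phases and Adam for the last. The default
#' sampling sizes are likewise the reference ones: 512 uniform batch points
#' on \[-3, 3\], 100 Fokker-Planck trajectories per point, 10 gradient
#' trajectories per point, step size 0.005. Reduced-scale runs pass smaller
#' values explicitly.
#'
#' @param phases A data frame with columns `iters`, `updates`, `optimizer`,
#'   `gamma1`, `gamma2`; one row per phase.
#' @param batch_points Batch size `K`.
#' @param box Sampling interval for the batch.
#' @param fp_samples Trajectories per point for the density solve.
#' @param bel_samples Trajectories per point for the gradient estimates.
#' @param lambda_degree Degree of the multiplier polynomial.
#' @param smooth_window Optional odd box-filter window applied to the
#'   estimated final density over the (sorted) batch before the multiplier
#'   update and the l1 report; `NULL` (default) keeps the raw estimator.
#' @param normalize Normalize the estimated final density over the batch
#'   grid before the multiplier update and the l1 report (default `FALSE`,
#'   the raw estimator).
#' @export
trainer_config <- function(phases = NULL, batch_points = 512, box = c(-3, 3),
                           fp_samples = 100, bel_samples = 10,
                           lambda_degree = 6, smooth_window = NULL,
                           normalize = FALSE) {
  if (is.null(phases)) {
    phases <- tibble::tibble(
      iters = c(20L, 20L, 20L, 20L),
      updates = c(100L, 100L, 400L, 400L),
      optimizer = c("sgd", "sgd", "sgd", "adam"),
      gamma1 = c(0.1, 1e-2, 1e-2, 1e-2),
      gamma2 = c(1e-3, 1e-4, 1e-5, 1e-4))
  }
  abort_if(any(phases$gamma1 < 0) || any(phases$gamma2 < 0),
           "learning rates must be non-negative.")
  structure(list(phases = tibble::as_tibble(phases),
                 batch_points = batch_points, box = box,
                 fp_samples = fp_samples, bel_samples = bel_samples,
                 lambda_degree = lambda_degree,
                 smooth_window = smooth_window, normalize = normalize),
            class = "trainer_config")
}

#' Learn a control protocol by gradient descent
#'
#' The coupled learning loop: at each outer iteration a fresh uniform batch
#' of positions is drawn; the final density under the current drift is
#' estimated by the Girsanov Fokker-Planck solver; the Lagrange multiplier
#' (the terminal value condition) takes an ascent step on the log density
#' ratio; the value-function gradient at every grid node is estimated by the
#' Bismut-Elworthy-Li formula with the current drift and terminal condition
#' `lambda`; and the drift model is fitted toward the stationarity targets
#' `(2 / beta) grad V` (the first-order optimality relation of the bridge
#' links force and value gradient through `grad V = (beta / 2) grad U`). The report tracks, per iteration, the weighted l1
#' distance of the estimated final density from the target marginal, the
#' final fit loss, and the mean absolute stationarity residual of the batch.
#'
#' @param bounds A [boundary_conditions()] (initial and final marginals).
#' @param model An [overdamped_model()] (supplies `mu`, `beta`).
#' @param grid A [time_grid()] over the control horizon.
#' @param config A [trainer_config()].
#' @param rng An [rng_stream()]; the whole run is reproducible from it.
#' @param drift Optional initial drift model (default: fresh [drift_nn()]
#'   seeded from `rng`).
#' @return An object of class `protocol_fit` with fields `drift`, `lambda`,
#'   `report` (tibble), `config`; see [tidy.protocol_fit()].
#' @export
train_protocol <- function(bounds, model, grid, config = trainer_config(),
                           rng = rng_stream(1), drift = NULL) {
  abort_if(!inherits(bounds, "bridge_bounds"), "need boundary_conditions().")
  if (is.null(drift)) drift <- drift_nn(rng = rng_spawn(rng, 999L))
  lambda <- multiplier_poly(config$lambda_degree)
  nodes <- grid$nodes
  N <- grid_n(grid)
  tf <- nodes[N + 1]
  # Fixed evaluation grid and a fixed noise seed for the report metric:
  # common random numbers across iterations make the first-to-last l1
  # comparison a paired one, so it reflects the drift, not the batch draw.
  q_eval <- seq(config$box[1], config$box[2],
                length.out = config$batch_points)
  pf_eval <- bounds$Pf(q_eval)
  eval_rng <- rng_spawn(rng, 777L)
  report <- list()
  iter <- 0L
  for (ph in seq_len(nrow(config$phases))) {
    phase <- config$phases[ph, ]
    for (l in seq_len(phase$iters)) {
      iter <- iter + 1L
      it_rng <- rng_spawn(rng, iter)
      qk <- sort(rng_runif(rng_spawn(it_rng, 1L), config$batch_points,
                           config$box[1], config$box[2]))
      pot <- drift_potential(drift)
      dyn <- overdamped_model(pot, mu = model$mu, beta = model$beta)
      # Final density under the current drift.
      est <- fp_density_overdamped(qk, tf, dyn, grid, bounds$log_Pi,
                                   M = config$fp_samples,
                                   rng = rng_spawn(it_rng, 2L),
                                   normalize = config$normalize,
                                   window = config$smooth_window)
      pf_vals <- bounds$Pf(qk)
      lambda <- update_multiplier(lambda, qk, est$mean, pf_vals, phase$gamma1)
      term <- function(q) multiplier_eval(lambda, q)
      # Stationarity targets (2 / beta) grad V at the interior nodes. The
      # terminal node is excluded: the gradient estimator's horizon is empty
      # there, and the raw lambda' it would contribute is the only target
      # not mollified by the heat flow, so it would dominate the fit.
      tgt <- vector("list", N)
      for (n in seq_len(N)) {
        gr <- bel_gradient_overdamped(qk, nodes[n], dyn, grid, term,
                                      running_cost = "bridge",
                                      M = config$bel_samples,
                                      rng = rng_spawn(it_rng, 10L + n),
                                      share_noise = FALSE)
        tgt[[n]] <- tibble::tibble(t = nodes[n], q = qk,
                                   target = (2 / model$beta) * gr$estimate)
      }
      targets <- dplyr::bind_rows(tgt)
      drift <- fit_drift(drift, targets, rate = phase$gamma2,
                         steps = phase$updates, optimizer = phase$optimizer)
      resid <- mean(abs(drift_eval(drift, targets$t, targets$q) -
                          targets$target))
      dyn_new <- overdamped_model(drift_potential(drift), mu = model$mu,
                                  beta = model$beta)
      est_eval <- fp_density_overdamped(q_eval, tf, dyn_new, grid, bounds$log_Pi,
                                        M = config$fp_samples,
                                        rng = eval_rng,
                                        normalize = config$normalize,
                                        window = config$smooth_window)
      report[[iter]] <- tibble::tibble(
        iteration = iter, phase = ph,
        l1 = sum(pf_eval * abs(est_eval$mean - pf_eval)),
        l1_batch = sum(pf_vals * abs(est$mean - pf_vals)),
        fit_loss = attr(drift, "loss"),
        stationarity = resid)
    }
  }
  structure(list(drift = drift, lambda = lambda,
                 report = dplyr::bind_rows(report),
                 config = config, bounds = bounds, model = model, grid = grid),
            class = "protocol_fit")
}

#' @export
print.protocol_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<protocol_fit: %d iterations, final l1 = %.4g, final loss = %.4g>\n",
              nrow(r), r$l1[nrow(r)], r$fit_loss[nrow(r)]))
  invisible(x)
}
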