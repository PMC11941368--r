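#' Time-dependent mechanical potentials
#'
#' A `potential` bundles the scalar field `U_t(q)` with its spatial gradient,
#' Hessian and (optionally) time derivative. Estimators only ever touch the
#' accessors they need: the Fokker-Planck solvers use the gradient, the
#' tangent-flow cocycles additionally need the Hessian, and the value `U`
#' itself is only required for equilibrium densities, so `value` and `hessian`
#' may be omitted when unavailable (e.g. for a learned drift that models
#' `grad U` directly).
#'
#' All accessors are vectorized over states: for dimension `d`, they receive
#' the time `t` and an `n x d` matrix of positions and must return a length-n
#' vector (`value`, and `hessian` when `d = 1`), an `n x d` matrix
#' (`gradient`), or an `n x d x d` array (`hessian`, `d > 1`). For `d = 1`,
#' plain vectorized functions of `q` are accepted.
#'
#' @param gradient Function `(t, q) -> grad U_t(q)`.
#' @param hessian Optional function `(t, q) -> Hessian of U_t`.
#' @param value Optional function `(t, q) -> U_t(q)`.
#' @param time_derivative Optional function `(t, q) -> dU_t/dt (q)`.
#' @param d State dimension (default 1).
#' @return An object of class `potential`.
#' @seealso [fixture_potential()] for the built-in analytic examples.
#' @export
potential <- function(gradient, hessian = NULL, value = NULL,
                      time_derivative = NULL, d = 1L) {
  abort_if(!is.function(gradient), "`gradient` must be a function(t, q).")
  structure(list(value = value, gradient = gradient, hessian = hessian,
                 time_derivative = time_derivative, d = as.integer(d)),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat(sprintf("<potential d=%d%s%s>\n", x$d,
              if (is.null(x$hessian)) ", no hessian" else "",
              if (is.null(x$value)) ", no value" else ""))
  invisible(x)
}

as_state_matrix <- function(q, d) {
  if (is.matrix(q)) {
    abort_if(ncol(q) != d, "state matrix has wrong dimension.")
    q
  } else {
    abort_if(d != 1, "vector states only allowed for d = 1.")
    matrix(q, ncol = 1)
  }
}

pot_value <- function(pot, t, q) {
  abort_if(is.null(pot$value), "this potential has no `value` accessor.")
  Q <- as_state_matrix(q, pot$d)
  as.numeric(pot$value(t, if (pot$d == 1) Q[, 1] else Q))
}

pot_grad <- function(pot, t, q) {
  Q <- as_state_matrix(q, pot$d)
  g <- pot$gradient(t, if (pot$d == 1) Q[, 1] else Q)
  if (!is.matrix(g)) g <- matrix(g, ncol = pot$d)
  g
}

# Returns n x d x d array (n x 1 x 1 for d = 1).
pot_hess <- function(pot, t, q) {
  abort_if(is.null(pot$hessian),
           "this operation needs the potential Hessian, which is not defined.")
  Q <- as_state_matrix(q, pot$d)
  h <- pot$hessian(t, if (pot$d == 1) Q[, 1] else Q)
  if (!is.array(h) || length(dim(h)) != 3)
    h <- array(h, dim = c(nrow(Q), pot$d, pot$d))
  h
}

#' Built-in analytic potentials
#'
#' The fixtures used throughout the examples and tests:
#' \describe{
#'   \item{`zero`}{`U = 0` (free diffusion).}
#'   \item{`harmonic`}{`U = k q^2 / 2`, the Ornstein-Uhlenbeck case.}
#'   \item{`cubic_grad`}{`U = q^4 / 2`, i.e. `dU/dq = 2 q^3`.}
#'   \item{`quartic_left_well`}{`U = (q - 1)^4 / 4`, a single well at q = 1.}
#'   \item{`double_well`}{`U = (q^2 - 1)^2 / 4`, `dU/dq = q^3 - q`.}
#' }
#' All are time-independent, one-dimensional, with analytic gradient and
#' Hessian.
#'
#' @param name One of the names above.
#' @param k Stiffness for `harmonic`.
#' @return A [potential()].
#' @export
fixture_potential <- function(name = c("zero", "harmonic", "cubic_grad",
                                       "quartic_left_well", "double_well"),
                              k = 1) {
  name <- match.arg(name)
  switch(name,
    zero = potential(
      value = function(t, q) rep(0, length(q)),
      gradient = function(t, q) rep(0, length(q)),
      hessian = function(t, q) rep(0, length(q)),
      time_derivative = function(t, q) rep(0, length(q))),
    harmonic = potential(
      value = function(t, q) k * q^2 / 2,
      gradient = function(t, q) k * q,
      hessian = function(t, q) rep(k, length(q)),
      time_derivative = function(t, q) rep(0, length(q))),
    cubic_grad = potential(
      value = function(t, q) q^4 / 2,
      gradient = function(t, q) 2 * q^3,
      hessian = function(t, q) 6 * q^2,
      time_derivative = function(t, q) rep(0, length(q))),
    quartic_left_well = potential(
      value = function(t, q) (q - 1)^4 / 4,
      gradient = function(t, q) (q - 1)^3,
      hessian = function(t, q) 3 * (q - 1)^2,
      time_derivative = function(t, q) rep(0, length(q))),
    double_well = potential(
      value = function(t, q) (q^2 - 1)^2 / 4,
      gradient = function(t, q) q^3 - q,
      hessian = function(t, q) 3 * q^2 - 1,
      time_derivative = function(t, q) rep(0, length(q))))
}

#' Check a potential's derivatives against finite differences
#'
#' Central finite differences of `value` are compared with `gradient`, and of
#' `gradient` with `hessian`, at the supplied probe points. Intended for
#' validating hand-coded potentials.
#'
#' @param pot A [potential()] with a `value` accessor.
#' @param t Probe time.
#' @param q Probe points (vector, d = 1).
#' @param step Finite-difference step.
#' @return A tibble with columns `q`, `grad_abs_err`, `hess_abs_err`,
#'   `max_rel_err`.
#' @export
check_potential <- function(pot, t, q, step = 1e-5) {
  abort_if(pot$d != 1, "finite-difference check implemented for d = 1.")
  gfd <- (pot_value(pot, t, q + step) - pot_value(pot, t, q - step)) / (2 * step)
  g <- pot_grad(pot, t, q)[, 1]
  hfd <- (pot_grad(pot, t, q + step)[, 1] - pot_grad(pot, t, q - step)[, 1]) /
    (2 * step)
  h <- pot_hess(pot, t, q)[, 1, 1]
  rel <- function(a, b) abs(a - b) / pmax(1, abs(a), abs(b))
  tibble::tibble(q = q,
                 grad_abs_err = abs(gfd - g),
                 hess_abs_err = abs(hfd - h),
                 max_rel_err = pmax(rel(gfd, g), rel(hfd, h)))
}
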