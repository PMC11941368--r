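#' Overdamped (Langevin-Smoluchowski) model
#'
#' The position-only diffusion
#' `dq_t = -mu (grad U_t)(q_t) dt + sqrt(2 mu / beta) dw_t`,
#' describing a particle whose inertia is negligible relative to friction.
#' `mu` is the motility (time over mass) and `1/beta` the bath temperature in
#' energy units.
#'
#' @param potential A [potential()].
#' @param mu Motility, `> 0`.
#' @param beta Inverse temperature, `> 0`.
#' @return An object of class `overdamped_model`.
#' @export
overdamped_model <- function(potential, mu = 1, beta = 1) {
  abort_if(!inherits(potential, "potential"), "`potential` must be a potential.")
  abort_if(mu <= 0 || beta <= 0, "`mu` and `beta` must be positive.")
  structure(list(potential = potential, mu = mu, beta = beta, d = potential$d),
            class = "overdamped_model")
}

#' Underdamped (Langevin-Kramers) model
#'
#' The phase-space diffusion
#' `dq_t = (p_t / m) dt`,
#' `dp_t = -(p_t / tau + (grad U_t)(q_t)) dt + sqrt(2 m / (tau beta)) dw_t`,
#' with mass `m`, Stokes friction time `tau` and inverse temperature `beta`.
#' Noise enters only the momentum, so the diffusion is degenerate
#' (hypoelliptic). The derived motility `mu = tau / m` links the model to its
#' overdamped limit.
#'
#' @param potential A [potential()].
#' @param m Mass, `> 0`.
#' @param tau Stokes time, `> 0`.
#' @param beta Inverse temperature, `> 0`.
#' @return An object of class `underdamped_model` (field `mu = tau / m`).
#' @export
underdamped_model <- function(potential, m = 1, tau = 1, beta = 1) {
  abort_if(!inherits(potential, "potential"), "`potential` must be a potential.")
  abort_if(m <= 0 || tau <= 0 || beta <= 0, "`m`, `tau`, `beta` must be positive.")
  structure(list(potential = potential, m = m, tau = tau, beta = beta,
                 mu = tau / m, d = potential$d),
            class = "underdamped_model")
}

#' @export
print.overdamped_model <- function(x, ...) {
  cat(sprintf("<overdamped_model mu=%g beta=%g d=%d>\n", x$mu, x$beta, x$d))
  invisible(x)
}

#' @export
print.underdamped_model <- function(x, ...) {
  cat(sprintf("<underdamped_model m=%g tau=%g beta=%g d=%d>\n",
              x$m, x$tau, x$beta, x$d))
  invisible(x)
}
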