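#' Reproducible random streams with per-trajectory substreams
#'
#' Monte Carlo estimators in this package draw their noise through an
#' `rng_stream`. Each sampled trajectory consumes its own L'Ecuyer-CMRG
#' substream, so estimates are bit-reproducible for a fixed seed and, when the
#' number of trajectories `M` grows, the first trajectories are unchanged.
#' The latter property is what makes variance-versus-M diagnostics meaningful:
#' sample sets at increasing M are nested.
#'
#' @param seed Integer seed (kept below 2^31).
#' @return An object of class `rng_stream`.
#' @examples
#' rng <- rng_stream(1)
#' a <- noise_array(rng, M = 4, n = 3)
#' b <- noise_array(rng, M = 8, n = 3)
#' stopifnot(identical(a, b[1:4, , , drop = FALSE]))
#' @export
rng_stream <- function(seed) {
  abort_if(!is.numeric(seed) || length(seed) != 1 || !is.finite(seed),
           "`seed` must be a single finite integer.")
  structure(list(seed = as.integer(seed %% 2147483647)), class = "rng_stream")
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream seed=", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Derive an independent child stream
#'
#' Distinct consumers of one user-facing seed (e.g. the Fokker-Planck solve
#' and the gradient estimates inside one training iteration) take children
#' keyed by small integers, so no two consumers share draws.
#'
#' @param rng An [rng_stream()].
#' @param key Integer key identifying the consumer.
#' @export
rng_spawn <- function(rng, key) {
  stopifnot(inherits(rng, "rng_stream"))
  rng_stream(derive_seed(rng$seed, key))
}

# Run expr with the global RNG temporarily seeded; restores prior state.
with_rng <- function(rng, expr) {
  old_kind <- RNGkind()
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(rng$seed)
  force(expr)
}

#' Standard-normal noise with nested per-trajectory substreams
#'
#' @param rng An [rng_stream()].
#' @param M Number of trajectories.
#' @param n Draws per trajectory (time steps).
#' @param d Noise dimension per step.
#' @return A numeric array of dimension `c(M, n, d)`.
#' @export
noise_array <- function(rng, M, n, d = 1L) {
  stopifnot(inherits(rng, "rng_stream"))
  abort_if(M < 1 || n < 0, "`M` must be >= 1 and `n` >= 0.")
  old_kind <- RNGkind()
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(rng$seed)
  s <- get(".Random.seed", envir = globalenv())
  out <- matrix(0, nrow = M, ncol = n * d)
  for (i in seq_len(M)) {
    s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, envir = globalenv())
    out[i, ] <- rnorm(n * d)
  }
  array(out, dim = c(M, n, d))
}

#' Uniform draws from a stream (batch sampling helper)
#' @inheritParams noise_array
#' @param min,max Range.
#' @keywords internal
rng_runif <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, runif(n, min, max))
}
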