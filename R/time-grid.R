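#' Time discretization of the control horizon
#'
#' A strictly increasing grid `t0 = t_0 < t_1 < ... < t_N = tf` on which all
#' trajectories are integrated by the Euler-Maruyama scheme. Either a step
#' size `dt` or a number of intervals `n` can be given; an explicit node
#' vector is also accepted (non-uniform grids are supported everywhere).
#'
#' @param t0,tf Horizon endpoints, `tf > t0`.
#' @param dt Target step size; the horizon is split into
#'   `ceiling((tf - t0) / dt)` equal intervals.
#' @param n Number of intervals (alternative to `dt`).
#' @param nodes Explicit, strictly increasing node vector (alternative to both).
#' @return An object of class `time_grid` with fields `nodes` (length N + 1)
#'   and `dt` (length N step sizes).
#' @examples
#' g <- time_grid(0, 0.2, dt = 0.005)
#' length(g$nodes)
#' @export
time_grid <- function(t0 = NULL, tf = NULL, dt = NULL, n = NULL, nodes = NULL) {
  if (is.null(nodes)) {
    abort_if(is.null(t0) || is.null(tf) || tf <= t0,
             "need `tf > t0` (or explicit `nodes`).")
    if (is.null(n)) {
      abort_if(is.null(dt) || dt <= 0, "give a positive `dt` or an integer `n`.")
      n <- max(1L, as.integer(ceiling((tf - t0) / dt - 1e-9)))
    }
    abort_if(n < 1, "`n` must be >= 1.")
    nodes <- seq(t0, tf, length.out = n + 1)
  }
  abort_if(length(nodes) < 2 || any(diff(nodes) <= 0),
           "`nodes` must be strictly increasing with at least two entries.")
  structure(list(nodes = as.numeric(nodes), dt = diff(as.numeric(nodes))),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid [%g, %g], %d intervals, dt ~ %g>\n",
              x$nodes[1], x$nodes[length(x$nodes)], length(x$dt), mean(x$dt)))
  invisible(x)
}

grid_n <- function(grid) length(grid$dt)

# Index of time t among the grid nodes (error if absent).
grid_index <- function(grid, t, tol = 1e-9) {
  i <- which(abs(grid$nodes - t) <= tol * max(1, abs(t)) + 1e-12)
  abort_if(length(i) != 1, sprintf("time %g is not a grid node.", t))
  i
}

# Sub-grid from node index i to the final node.
grid_tail <- function(grid, i) {
  if (i == length(grid$nodes)) return(NULL)
  time_grid(nodes = grid$nodes[i:length(grid$nodes)])
}
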