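# Internal numeric helpers shared across the estimators.

#' @importFrom stats rnorm runif sd approx splinefun integrate lm coef
#' @importFrom utils head tail
NULL

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(NULL)
}

#' Log-sum-exp and log-mean-exp reductions
#'
#' Numerically stable reductions used wherever Girsanov weights or bridge
#' potentials are accumulated in log space.
#'
#' @param x Numeric vector of log values. `-Inf` entries are allowed.
#' @return A single numeric value.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Row-wise log-mean-exp over the columns of a matrix.
row_logmeanexp <- function(X) {
  m <- apply(X, 1L, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowMeans(exp(X[ok, , drop = FALSE] - m[ok])))
  out
}

#' Trapezoid quadrature on an ordered grid
#' @param x Ordered abscissae.
#' @param y Values at `x`.
#' @return The trapezoid-rule integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  abort_if(length(y) != n, "`x` and `y` must have equal length.")
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Effective sample size of normalized importance weights given log weights.
ess_from_logw <- function(logw) {
  lw <- logw - logsumexp(logw)
  1 / sum(exp(2 * lw))
}

# Deterministic 31-bit sub-seed derivation (golden-ratio hashing), so that
# distinct consumers of one user seed receive unrelated streams.
derive_seed <- function(seed, key) {
  s <- (as.double(seed) * 2654435761 + as.double(key) * 40503 + 1013904223) %% 2147483647
  as.integer(s)
}
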