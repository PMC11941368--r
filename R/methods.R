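#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved bridge into long form
#'
#' One row per (time node, point) with the bridge potentials, the
#' reconstructed density and value function, and the optimal drift.
#'
#' @param x An `sb_bridge` from [half_bridge_solve()].
#' @param normalize Normalize the density within each time node (trapezoid
#'   mass one over the point grid).
#' @param ... Unused.
#' @return A tibble: `time`, `q`, `log_phi`, `log_phihat`, `p`, `V`, `dU`.
#' @method tidy sb_bridge
#' @export
tidy.sb_bridge <- function(x, normalize = TRUE, ...) {
  nodes <- x$grid$nodes
  P <- length(x$points)
  out <- tibble::tibble(
    time = rep(nodes, each = P),
    q = rep(x$points, times = length(nodes)),
    log_phi = as.numeric(t(x$log_phi)),
    log_phihat = as.numeric(t(x$log_phihat)),
    p = as.numeric(t(exp(x$log_p))),
    V = as.numeric(t(x$V)),
    dU = as.numeric(t(x$dU)))
  if (normalize) {
    out <- dplyr::mutate(dplyr::group_by(out, .data$time),
                         p = .data$p / trapz(.data$q, .data$p))
    out <- dplyr::ungroup(out)
  }
  out
}

#' One-row summary of a solved bridge
#'
#' Reports how well the reconstruction pins the two assigned marginals
#' (weighted l1 distances over the point grid), the sweep count, the last
#' relative change of the final-density reconstruction, and the number of
#' floored half-bridge divisions. Both marginal distances are genuine
#' residuals of the iteration: the final one uses the last pre-reset
#' reconstruction `phi_tf * phihat_tf` (after the boundary reset the product
#' equals the target identically), and the initial one uses the stored state,
#' in which `phihat_ti` predates the sweep's backward update of `phi`.
#'
#' @param x An `sb_bridge`.
#' @param ... Unused.
#' @method glance sb_bridge
#' @export
glance.sb_bridge <- function(x, ...) {
  pts <- x$points
  p_i <- exp(x$log_p[1, ]); p_i <- p_i / trapz(pts, p_i)
  p_f <- x$p_tf_candidate; p_f <- p_f / trapz(pts, p_f)
  Pi_ <- x$bounds$Pi(pts); Pf_ <- x$bounds$Pf(pts)
  tibble::tibble(
    l1_initial = sum(Pi_ * abs(p_i - Pi_)),
    l1_final = sum(Pf_ * abs(p_f - Pf_)),
    iterations = x$iterations,
    last_change = if (length(x$convergence)) utils::tail(x$convergence, 1)
                  else NA_real_,
    floored = x$floor_count)
}

#' Training report of a protocol fit
#' @param x A `protocol_fit` from [train_protocol()].
#' @param ... Unused.
#' @method tidy protocol_fit
#' @export
tidy.protocol_fit <- function(x, ...) x$report

#' One-row summary of a protocol fit
#' @param x A `protocol_fit`.
#' @param ... Unused.
#' @method glance protocol_fit
#' @export
glance.protocol_fit <- function(x, ...) {
  r <- x$report
  tibble::tibble(iterations = nrow(r),
                 l1_first = r$l1[1], l1_final = r$l1[nrow(r)],
                 fit_loss = r$fit_loss[nrow(r)],
                 stationarity = r$stationarity[nrow(r)])
}

#' Plot a pointwise density estimate
#'
#' Estimated density with a 3-standard-error ribbon against the query points.
#'
#' @param object A `density_estimate` tibble.
#' @param ... Unused.
#' @method autoplot density_estimate
#' @export
autoplot.density_estimate <- function(object, ...) {
  abort_if(!("q" %in% names(object)) || "p" %in% names(object),
           "autoplot is implemented for 1-d position densities.")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 3 * .data$se,
                                      ymax = .data$mean + 3 * .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "q", y = "density",
                  subtitle = sprintf("M = %s trajectories per point",
                                     format(attr(object, "M"))))
}

#' Plot the evolution of a solved bridge
#'
#' Density profiles at a selection of time nodes, with the assigned
#' boundary marginals overlaid at the endpoints.
#'
#' @param object An `sb_bridge`.
#' @param times Time nodes to show (default: 4 evenly spaced).
#' @param ... Unused.
#' @method autoplot sb_bridge
#' @export
autoplot.sb_bridge <- function(object, times = NULL, ...) {
  nodes <- object$grid$nodes
  if (is.null(times)) times <- nodes[unique(round(seq(1, length(nodes),
                                                      length.out = 4)))]
  df <- dplyr::filter(tidy(object), .data$time %in% times)
  bnd <- dplyr::bind_rows(
    tibble::tibble(time = nodes[1], q = object$points,
                   target = object$bounds$Pi(object$points)),
    tibble::tibble(time = nodes[length(nodes)], q = object$points,
                   target = object$bounds$Pf(object$points)))
  bnd <- dplyr::filter(bnd, .data$time %in% times)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$p)) +
    ggplot2::geom_area(data = bnd, ggplot2::aes(y = .data$target),
                       alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "q", y = "density")
}

#' Plot a training report
#'
#' Final-marginal l1 distance and drift fit loss per outer iteration.
#'
#' @param object A `protocol_fit`.
#' @param ... Unused.
#' @method autoplot protocol_fit
#' @export
autoplot.protocol_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report,
                            c("l1", "fit_loss", "stationarity"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "outer iteration", y = NULL)
}

#' @importFrom rlang .data
NULL
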