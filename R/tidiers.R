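#' Tidy a diffusion-exponent fit
#'
#' @param x A `diffusion_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity (`eta`, `G`).
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("eta", "G"), estimate = c(x$eta, x$G))
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(eta = x$eta, G = x$G, r.squared = x$r2,
                 n_lags = length(x$lags), n_trajectories = x$n)
}

#' Tidy a power-law tail fit
#'
#' @param x A `powerlaw_fit` object.
#' @param ... Unused.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha_hat)
}

#' @rdname tidy.powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha_hat, xmin = x$xmin, n_tail = x$n_tail)
}

#' Plot a simulated bump trajectory
#'
#' Decoded bump position over time.
#'
#' @param object A `can_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.can_sim <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$time, .data$z)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "decoded position (m)",
                  title = sprintf("CAN bump trajectory (m = %g, gamma = %g)",
                                  object$params$m, object$params$gamma)) +
    ggplot2::ylim(0, object$params$L)
}

#' Plot a diffusion-exponent fit
#'
#' Mean distance versus lag on log-log axes with the fitted power law.
#'
#' @param object A `diffusion_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  df <- tibble::tibble(lag = object$lags, mean_dist = object$mean_dist)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$mean_dist)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = object$G * .data$lag^object$eta),
                       colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (bins)", y = "mean distance",
                  title = sprintf("eta = %.3f", object$eta))
}

#' Plot an eigenvalue spectrum (rescaling ratios)
#'
#' @param object A `can_spectrum` tibble with a `ratio` column (see
#'   [perturbed_eigenvalues()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.can_spectrum <- function(object, ...) {
  if (!"ratio" %in% names(object)) {
    stop("spectrum has no perturbation ratios; supply a perturbation",
         call. = FALSE)
  }
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$k, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mode k", y = "|perturbed| / |unperturbed|")
}

#' Plot a phase profile
#'
#' Per-bin means against oscillation phase, with the circular weighted mean
#' marked.
#'
#' @param object A `phase_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_profile <- function(object, ...) {
  df <- tibble::tibble(phase = object$phase_bins, value = object$mean_value)
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$circ_mean, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "oscillation phase (rad)", y = "mean value")
}

#' Plot a replay-diffusivity phase diagram
#'
#' @param pd Tibble from [phase_diagram()].
#' @return A ggplot object (alpha as fill over the m-gamma plane).
#' @export
plot_phase_diagram <- function(pd) {
  ggplot2::ggplot(pd, ggplot2::aes(.data$m, .data$gamma, fill = .data$alpha)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "adaptation strength m", y = "noise level gamma",
                  fill = "alpha")
}
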