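#' Reduce the network to its 1-D Langevin position dynamics
#'
#' Projects the network dynamics onto the bump height and position modes and
#' collapses them (with bump heights replaced by their stationary means) into
#' a two-variable Langevin system for the bump position `z` and the
#' displacement `s` between the activity bump and the lagging adaptation
#' bump:
#' \deqn{\tau_u \, dz = m s \, dt + a_z \, dW_z,}
#' \deqn{\tau_v \, ds = -(\mu + \gamma \xi) s \, dt + a_s \, dW_s,}
#' with `mu = 1 - tau_v * m / tau_u` the normalised distance of the
#' adaptation strength to the motion boundary and `gamma` the normalised
#' adaptation-noise level.
#'
#' @param params A [can_params()] object (a bump solution must exist).
#' @return An object of class `reduced_params`: list with `mu`, `gamma`,
#'   `sigma_s`, `a_z`, `a_s`, `Au_bar`, `Av_bar`, `m`, `tau_u`, `tau_v`, `a`.
#'   `sigma_s` is the displacement scale
#'   `sqrt((sqrt(2)*tau_v*sigma_U / (sqrt(pi)*tau_u*Au))^2 + (sqrt(2)*a*gamma)^2)`
#'   and coincides with the effective noise amplitude `a_s`.
#' @examples
#' rp <- reduce_params(can_params(m = 0.019, gamma = 0.95))
#' rp$mu                       # 0.088: just below the motion boundary
#' alpha_exponent(rp$mu, rp$gamma)
#' @export
reduce_params <- function(params) {
  amp <- bump_amplitude_theory(params)  # errors if no bump
  Au <- amp$Au
  mu <- 1 - params$tau_v * params$m / params$tau_u
  # sigma_m / m == 2*sqrt(pi)*a*gamma by the definition of gamma; use that
  # form so m = 0 stays well-defined.
  sm_over_m <- 2 * sqrt(pi) * params$a * params$gamma
  a_z <- sqrt(2 / pi) * params$sigma_U / Au
  a_s <- sqrt(2 / pi * (params$tau_v * params$sigma_U / (params$tau_u * Au))^2 +
                sm_over_m^2 / (2 * pi))
  sigma_s <- sqrt((sqrt(2) * params$tau_v * params$sigma_U /
                     (sqrt(pi) * params$tau_u * Au))^2 +
                    (sqrt(2) * params$a * params$gamma)^2)
  structure(list(mu = mu, gamma = params$gamma, sigma_s = sigma_s,
                 a_z = a_z, a_s = a_s, Au_bar = Au, Av_bar = params$m * Au,
                 m = params$m, tau_u = params$tau_u, tau_v = params$tau_v,
                 a = params$a),
            class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("<reduced_params> mu = %.4g, gamma = %.4g, sigma_s = %.4g\n",
              x$mu, x$gamma, x$sigma_s))
  cat(sprintf("  a_z = %.4g, a_s = %.4g, Au_bar = %.4g\n", x$a_z, x$a_s,
              x$Au_bar))
  if (x$gamma > 0) {
    cat(sprintf("  step-size tail exponent alpha = %.4g\n",
                alpha_exponent(x$mu, x$gamma)))
  }
  invisible(x)
}

#' Power-law step-size exponent of the bump trajectory
#'
#' The stationary displacement distribution implies step sizes with tail
#' `p(|dz|) ~ |dz|^(-1-alpha)` where `alpha = 1 + 2*mu/gamma^2`. Values
#' `alpha >= 2` correspond to Brownian diffusion, `0 < alpha < 2` to
#' superdiffusive (Levy-type) motion.
#'
#' @param mu Normalised distance to the motion boundary (may be negative).
#' @param gamma Normalised adaptation-noise level (> 0).
#' @return The exponent `alpha` (vectorised over `mu` and `gamma`).
#' @export
alpha_exponent <- function(mu, gamma) {
  if (any(gamma <= 0)) {
    stop("alpha is defined only for gamma > 0; with gamma = 0 the ",
         "displacement follows an OU process and the trajectory is Brownian",
         call. = FALSE)
  }
  1 + 2 * mu / gamma^2
}

#' Stationary density of the bump-adaptation displacement
#'
#' The Fokker-Planck stationary solution of the displacement dynamics is the
#' power-law family `p(s) = c0 * (sigma_s^2 + gamma^2 s^2)^-(1 + mu/gamma^2)`,
#' with `c0` computed by numerical normalisation on
#' `|s| <= support_mult * sigma_s / gamma`.
#'
#' @param rp A [reduce_params()] object with `gamma > 0`.
#' @param support_mult Half-width of the normalisation support in units of
#'   `sigma_s / gamma` (default 50).
#' @return An object of class `s_density`: list with `pdf` (a vectorised
#'   density function), `c0`, `support` and the shape parameters.
#' @export
stationary_s_density <- function(rp, support_mult = 50) {
  if (rp$gamma <= 0) {
    stop("stationary displacement density requires gamma > 0", call. = FALSE)
  }
  expo <- 1 + rp$mu / rp$gamma^2
  if (expo <= 1 / 2) {
    stop("non-normalizable configuration: mu/gamma^2 <= -1/2", call. = FALSE)
  }
  smax <- support_mult * rp$sigma_s / rp$gamma
  kernel <- function(s) (rp$sigma_s^2 + rp$gamma^2 * s^2)^(-expo)
  norm <- 2 * stats::integrate(kernel, 0, smax, rel.tol = 1e-10,
                               subdivisions = 1000L)$value
  c0 <- 1 / norm
  structure(list(pdf = function(s) {
    out <- c0 * kernel(s)
    out[abs(s) > smax] <- 0
    out
  }, c0 = c0, support = c(-smax, smax), mu = rp$mu, gamma = rp$gamma,
  sigma_s = rp$sigma_s), class = "s_density")
}

#' Simulate the reduced Langevin position dynamics
#'
#' Euler-Maruyama integration (Ito convention) of the reduced system; the
#' white noises are taken per unit of the respective rescaled time (`t/tau_v`
#' for the displacement, `t/tau_u` for the position), the convention under
#' which the stationary displacement law of [stationary_s_density()] is the
#' exact Fokker-Planck solution.
#'
#' @param rp A [reduce_params()] object.
#' @param duration Duration in ms.
#' @param dt Integration step in ms (default 0.1; must be small relative to
#'   `tau_u`).
#' @param seed Optional integer seed.
#' @param record_every Record every this many steps (default: every step).
#' @param z0,s0 Initial position and displacement.
#' @return A tibble with columns `time` (ms), `z` (unwrapped position) and
#'   `s` (displacement).
#' @export
simulate_langevin <- function(rp, duration, dt = 0.1, seed = NULL,
                              record_every = 1L, z0 = 0, s0 = 0) {
  if (dt >= rp$tau_u) {
    stop("`dt` must be small relative to tau_u", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- langevin_simulate_cpp(rp$mu, rp$gamma, rp$a_z, rp$a_s, rp$m,
                               rp$tau_u, rp$tau_v, dt,
                               as.integer(round(duration / dt)),
                               as.integer(record_every), z0, s0)
  tibble::tibble(time = as.numeric(res$times), z = as.numeric(res$z),
                 s = as.numeric(res$s))
}

#' Phase diagram of replay diffusivity
#'
#' Evaluates the step-size exponent `alpha = 1 + 2*mu/gamma^2` on a grid of
#' adaptation strengths and noise levels and classifies each point into a
#' regime: `"stationary"` (adaptation below the motion boundary and noise
#' below `stationary_gamma`), `"diffusive"` (`alpha >= 2`, clipped to 2) or
#' `"superdiffusive"` (`alpha < 2`). Exponent values above 2 are clipped to
#' 2; non-positive values (deep in the supra-threshold regime, where mean and
#' variance of the step size diverge) are reported as `NA`.
#'
#' @param m_values,gamma_values Numeric grids (gamma values must be > 0).
#' @param params Baseline [can_params()] whose `m` and `gamma` are swept.
#' @param stationary_gamma Noise threshold below which sub-boundary points
#'   are labelled stationary (default 0.1).
#' @return A tibble with columns `m`, `gamma`, `mu`, `alpha`, `regime`.
#' @examples
#' pd <- phase_diagram(seq(0.002, 0.02, by = 0.002), c(0.05, 0.6, 0.95),
#'                     can_params())
#' @export
phase_diagram <- function(m_values, gamma_values, params = can_params(),
                          stationary_gamma = 0.1) {
  stopifnot(length(m_values) > 0, length(gamma_values) > 0,
            all(gamma_values > 0))
  m0 <- transition_boundary(params)
  grid <- tidyr::expand_grid(m = m_values, gamma = gamma_values)
  grid |>
    dplyr::mutate(
      mu = 1 - params$tau_v * .data$m / params$tau_u,
      alpha_raw = alpha_exponent(.data$mu, .data$gamma),
      regime = dplyr::case_when(
        .data$m < m0 & .data$gamma < stationary_gamma ~ "stationary",
        .data$alpha_raw >= 2 ~ "diffusive",
        TRUE ~ "superdiffusive"
      ),
      alpha = dplyr::case_when(
        .data$alpha_raw > 2 ~ 2,
        .data$alpha_raw <= 0 ~ NA_real_,
        TRUE ~ .data$alpha_raw
      )
    ) |>
    dplyr::select("m", "gamma", "mu", "alpha", "regime")
}

#' Project a network snapshot onto the bump motion modes
#'
#' Computes the inner products of the synaptic profile with the height mode
#' `u0(x|z)` (a Gaussian centred on `z`) and the position mode `u1(x|z)` (its
#' antisymmetric first derivative shape) under the ring measure. The height
#' coefficient scales with the bump amplitude; the position coefficient is
#' zero for a bump exactly centred on `z` and changes sign with small
#' displacements. Diagnostic companion of the Langevin reduction.
#'
#' @param U Synaptic input vector (length `N`).
#' @param z Reference position (m).
#' @param params A [can_params()] object.
#' @return List with elements `height` and `position`.
#' @export
project_modes <- function(U, z, params) {
  stopifnot(length(U) == params$N)
  xs <- neuron_positions(params)
  dx <- params$L / params$N
  d <- ring_diff(xs, z, params$L)
  g <- exp(-d^2 / (4 * params$a^2))
  u0 <- g / (params$a * sqrt(2 * pi))
  u1 <- d * g / (params$a^2 * sqrt(2 * pi))
  list(height = sum(U * u0) * dx, position = sum(U * u1) * dx)
}
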