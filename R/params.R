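#' Construct the parameter set of the 1-D CAN model with firing-rate adaptation
#'
#' Bundles every constant of the continuous attractor network (CAN) with
#' firing-rate adaptation (FRA) on a periodic track of circumference
#' `L = N / rho`. Defaults are the common settings used throughout the
#' package's simulations: `N = 128` neurons at density `rho = 20` per metre
#' (so `L = 6.4` m), Gaussian recurrent connectivity of range `a = 0.4` m and
#' strength `J0 = 4`, divisive global inhibition `k = 20`, time constants
#' `tau_u = 1` ms (synaptic) and `tau_v = 48` ms (adaptation), and Euler step
#' `dt = 0.1` ms.
#'
#' The adaptation-noise amplitude is never supplied directly: the user-facing
#' knob is the normalised noise level `gamma`, and the multiplicative noise
#' amplitude is derived as `sigma_m = 2 * sqrt(pi) * a * m * gamma`.
#'
#' @param N Number of neurons (>= 8).
#' @param rho Neuron density (neurons per metre of track).
#' @param a Recurrent interaction range (m); also the Gaussian width of the
#'   external location input.
#' @param J0 Recurrent connection strength.
#' @param k Global (divisive) inhibition strength.
#' @param tau_u Synaptic time constant (ms).
#' @param tau_v Adaptation time constant (ms); must exceed `tau_u`.
#' @param m Adaptation strength (dimensionless negative-feedback gain).
#' @param sigma_U Additive noise amplitude on the synaptic input `U`.
#' @param gamma Normalised adaptation-noise level; `sigma_m` is derived from it.
#' @param beta Location-input strength (0 in replay mode).
#' @param v_ext External movement speed (m/s) of the location input.
#' @param A_gamma,omega_gamma,phi_gamma Amplitude, angular frequency (rad/s)
#'   and initial phase of the spatially uniform oscillatory drive.
#' @param dt Euler integration step (ms).
#'
#' @return An object of class `can_params`: a named list with all fields above
#'   plus the derived track length `L = N / rho` (m) and `sigma_m`.
#' @examples
#' p <- can_params(m = 0.07)
#' p$L              # 6.4 m track
#' bump_exists(p)   # TRUE: inhibition below the bump-existence threshold
#' @export
can_params <- function(N = 128L, rho = 20, a = 0.4, J0 = 4, k = 20,
                       tau_u = 1, tau_v = 48, m = 0, sigma_U = 5e-4,
                       gamma = 0, beta = 0, v_ext = 0,
                       A_gamma = 0.5, omega_gamma = 30, phi_gamma = 0,
                       dt = 0.1) {
  N <- as.integer(N)
  if (N < 8L) stop("`N` must be at least 8", call. = FALSE)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (rho <= 0) stop("`rho` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!(tau_v > tau_u && tau_u > 0)) {
    stop("time constants must satisfy tau_v > tau_u > 0", call. = FALSE)
  }
  if (gamma < 0) stop("`gamma` must be nonnegative", call. = FALSE)
  if (sigma_U < 0) stop("`sigma_U` must be nonnegative", call. = FALSE)
  if (beta < 0) stop("`beta` must be nonnegative", call. = FALSE)
  p <- list(
    N = N, rho = rho, a = a, J0 = J0, k = k,
    tau_u = tau_u, tau_v = tau_v, m = m,
    sigma_U = sigma_U, gamma = gamma,
    sigma_m = 2 * sqrt(pi) * a * m * gamma,
    beta = beta, v_ext = v_ext,
    A_gamma = A_gamma, omega_gamma = omega_gamma, phi_gamma = phi_gamma,
    dt = dt, L = N / rho
  )
  structure(p, class = "can_params")
}

#' @export
print.can_params <- function(x, ...) {
  cat("<can_params>\n")
  cat(sprintf("  N = %d neurons, rho = %g /m, L = %g m\n", x$N, x$rho, x$L))
  cat(sprintf("  a = %g m, J0 = %g, k = %g\n", x$a, x$J0, x$k))
  cat(sprintf("  tau_u = %g ms, tau_v = %g ms, dt = %g ms\n",
              x$tau_u, x$tau_v, x$dt))
  cat(sprintf("  m = %g (boundary m0 = %g), gamma = %g, sigma_U = %g\n",
              x$m, transition_boundary(x), x$gamma, x$sigma_U))
  if (x$beta > 0) {
    cat(sprintf("  location input: beta = %g, v_ext = %g m/s\n",
                x$beta, x$v_ext))
  }
  invisible(x)
}

#' Neuron positions on the ring
#'
#' Uniform placement `x_i = i * L / N`, `i = 0, ..., N-1`.
#'
#' @param params A [can_params()] object.
#' @return Numeric vector of length `N` with positions in `[0, L)`.
#' @export
neuron_positions <- function(params) {
  (seq_len(params$N) - 1) * params$L / params$N
}

#' Wrapped (circular) distance on the ring
#'
#' @param x,y Positions (recycled).
#' @param L Ring circumference.
#' @return Elementwise shortest distance along the ring, in `[0, L/2]`.
#' @export
ring_distance <- function(x, y, L) {
  d <- abs(x - y) %% L
  pmin(d, L - d)
}

#' Signed wrapped difference on the ring
#'
#' Returns `x - y` mapped to `(-L/2, L/2]`.
#'
#' @inheritParams ring_distance
#' @export
ring_diff <- function(x, y, L) {
  d <- (x - y) %% L
  ifelse(d > L / 2, d - L, d)
}

#' Does a stationary activity bump exist?
#'
#' The divisive global inhibition admits a Gaussian bump fixed point only when
#' the inhibition strength is below a threshold set by density, recurrent
#' strength and interaction range: `k < rho * J0^2 / (8 * sqrt(2*pi) * a)`.
#'
#' @param params A [can_params()] object.
#' @return Logical scalar.
#' @export
bump_exists <- function(params) {
  params$k < params$rho * params$J0^2 / (8 * sqrt(2 * pi) * params$a)
}

#' Theoretical bump amplitudes of the adaptation-free network
#'
#' Solves the Gaussian-ansatz fixed point of the noise-free, adaptation-free
#' network. The synaptic bump `U(x) = Au * exp(-(x - z)^2 / (4 a^2))` has
#' height (stable, plus branch)
#' `Au = (rho*J0 + sqrt(rho^2*J0^2 - 8*sqrt(2*pi)*k*rho*a)) / (4*sqrt(pi)*k*rho*a)`
#' and the rate bump height is `Ar = sqrt(2) * Au / (rho * J0)`.
#'
#' @param params A [can_params()] object.
#' @return A list with elements `Au`, `Ar` and `exists`. When no bump solution
#'   exists (inhibition above threshold) an error is signalled.
#' @examples
#' bump_amplitude_theory(can_params())  # Au ~ 0.120 with the default constants
#' @export
bump_amplitude_theory <- function(params) {
  if (!bump_exists(params)) {
    stop("no bump solution: global inhibition k is above the existence threshold ",
         sprintf("%.4g", params$rho * params$J0^2 / (8 * sqrt(2 * pi) * params$a)),
         call. = FALSE)
  }
  disc <- params$rho^2 * params$J0^2 -
    8 * sqrt(2 * pi) * params$k * params$rho * params$a
  Au <- (params$rho * params$J0 + sqrt(disc)) /
    (4 * sqrt(pi) * params$k * params$rho * params$a)
  list(Au = Au, Ar = sqrt(2) * Au / (params$rho * params$J0), exists = TRUE)
}

#' Transition boundary of intrinsic bump motion
#'
#' Below `m0 = tau_u / tau_v` the bump is stationary in the absence of noise;
#' above it, adaptation destabilises the bump and it travels at the intrinsic
#' speed given by [intrinsic_speed()].
#'
#' @param params A [can_params()] object.
#' @return The boundary adaptation strength `m0`.
#' @export
transition_boundary <- function(params) {
  params$tau_u / params$tau_v
}

#' Intrinsic speed of the activity bump under adaptation
#'
#' For adaptation strength above the boundary `m0 = tau_u/tau_v`, the
#' noise-free bump travels at
#' `v_int = (2 a / tau_v) * sqrt(m*tau_v/tau_u - sqrt(m*tau_v/tau_u))`;
#' below the boundary the speed is 0.
#'
#' @param params A [can_params()] object; its `m` field is used unless `m` is
#'   given.
#' @param m Optional adaptation strength(s) overriding `params$m`; vectorised.
#' @return Intrinsic speed(s) in track-length units per ms.
#' @examples
#' intrinsic_speed(can_params(), m = c(0.03, 0.05, 0.07))
#' @export
intrinsic_speed <- function(params, m = params$m) {
  ratio <- m * params$tau_v / params$tau_u
  v <- ifelse(ratio > 1, (2 * params$a / params$tau_v) *
                sqrt(pmax(ratio - sqrt(ratio), 0)), 0)
  as.numeric(v)
}
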