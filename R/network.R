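#' Recurrent connectivity matrix of the ring network
#'
#' Translation-invariant Gaussian connectivity on the periodic track:
#' `J[i, j] = J0 / (2*pi*a^2) * exp(-d(x_i, x_j)^2 / (2*a^2))` with `d` the
#' wrapped circular distance. Under the uniform neuron placement the matrix is
#' symmetric and circulant.
#'
#' @param params A [can_params()] object.
#' @return An `N x N` numeric matrix.
#' @export
build_connectivity <- function(params) {
  xs <- neuron_positions(params)
  d <- ring_distance(outer(xs, xs, "-"), 0, params$L)
  params$J0 / (2 * pi * params$a^2) * exp(-d^2 / (2 * params$a^2))
}

#' Firing rate under divisive global inhibition
#'
#' `r_i = U_i^2 / (1 + k * rho * sum_j U_j^2 * dx)` with `dx = L/N` the
#' spatial integration measure. Rates are nonnegative by construction and the
#' population rate saturates as the input grows.
#'
#' @param U Numeric vector of synaptic inputs (length `N`).
#' @param params A [can_params()] object.
#' @return Nonnegative rate vector of length `N`.
#' @export
firing_rate <- function(U, params) {
  stopifnot(length(U) == params$N)
  dx <- params$L / params$N
  U^2 / (1 + params$k * params$rho * sum(U^2) * dx)
}

#' Location-dependent external input
#'
#' A Gaussian bump of strength `beta` centred on the animal's position
#' `v_ext * t` (wrapped on the ring), conveying the physical location to the
#' network. With `beta = 0` (replay mode) the input vanishes.
#'
#' @param params A [can_params()] object.
#' @param t Time in ms (`v_ext` is in m/s).
#' @return Input vector of length `N`.
#' @export
location_input <- function(params, t) {
  if (params$beta == 0) return(numeric(params$N))
  xs <- neuron_positions(params)
  centre <- (params$v_ext / 1000 * t) %% params$L
  params$beta * exp(-ring_distance(xs, centre, params$L)^2 / (2 * params$a^2))
}

#' Spatially uniform oscillatory input
#'
#' `I(t) = A * sin(omega * t + phi)` applied identically to every neuron,
#' mimicking a slow rhythmic drive (e.g. slow gamma) during rest. `omega` is
#' in rad/s and `t` in ms.
#'
#' @inheritParams location_input
#' @return Input vector of length `N`.
#' @export
gamma_input <- function(params, t) {
  rep(params$A_gamma * sin(params$omega_gamma * t / 1000 + params$phi_gamma),
      params$N)
}

#' One Euler-Maruyama step of the network dynamics
#'
#' Reference R implementation of a single integration step; the main
#' [simulate_can()] driver runs the same update in compiled code. The
#' synaptic input relaxes towards recurrent excitation minus adaptation plus
#' external input; adaptation low-pass filters the synaptic input with gain
#' `m` and multiplicative noise (Ito convention, pre-step `U`).
#'
#' @param state List with elements `U`, `V`, `t` (a `NetworkState`).
#' @param params A [can_params()] object.
#' @param J Connectivity matrix from [build_connectivity()].
#' @param input External input vector (length `N`).
#' @return Updated state list with recomputed rate vector `r`.
#' @export
euler_step <- function(state, params, J, input = numeric(params$N)) {
  dx <- params$L / params$N
  r <- firing_rate(state$U, params)
  U_old <- state$U
  etaU <- if (params$sigma_U > 0) stats::rnorm(params$N) else numeric(params$N)
  etaV <- if (params$sigma_m > 0) stats::rnorm(params$N) else numeric(params$N)
  U <- U_old + (params$dt / params$tau_u) *
    (-U_old + params$rho * dx * as.numeric(J %*% r) - state$V + input) +
    (params$sigma_U / params$tau_u) * sqrt(params$dt) * etaU
  V <- state$V + (params$dt / params$tau_v) * (-state$V + params$m * U_old) +
    (params$sigma_m / params$tau_v) * sqrt(params$dt) * (U_old * etaV)
  if (!all(is.finite(U)) || !all(is.finite(V))) {
    stop(sprintf("unstable step at t = %g ms (dt = %g)", state$t, params$dt),
         call. = FALSE)
  }
  list(U = U, V = V, r = firing_rate(U, params), t = state$t + params$dt)
}

#' Decode the bump centre by circular centroid
#'
#' Maps the rate vector to the angle of `sum_i r_i * exp(2*pi*1i*x_i/L)` and
#' back to a ring position in `[0, L)`. Translation-equivariant: rotating the
#' rates by one neuron shifts the decoded position by `L/N`.
#'
#' @param r Nonnegative rate vector of length `N`.
#' @param params A [can_params()] object.
#' @return Decoded position in `[0, L)`.
#' @export
decode_bump_centre <- function(r, params) {
  if (all(r == 0)) {
    stop("cannot decode bump centre: all rates are zero", call. = FALSE)
  }
  xs <- neuron_positions(params)
  ang <- atan2(sum(r * sin(2 * pi * xs / params$L)),
               sum(r * cos(2 * pi * xs / params$L)))
  (ang / (2 * pi) * params$L) %% params$L
}

#' Gaussian bump profile of the synaptic input
#'
#' The fixed-point ansatz `U(x) = Au * exp(-d(x, centre)^2 / (4 a^2))`,
#' evaluated on the neuron grid. Used to initialise simulations at the
#' theoretical bump.
#'
#' @param params A [can_params()] object.
#' @param centre Bump centre position (m).
#' @param Au Bump height; defaults to the theoretical fixed-point height.
#' @return Numeric vector of length `N`.
#' @export
bump_profile <- function(params, centre = params$L / 2,
                         Au = bump_amplitude_theory(params)$Au) {
  xs <- neuron_positions(params)
  Au * exp(-ring_distance(xs, centre, params$L)^2 / (4 * params$a^2))
}

#' Simulate the CAN with firing-rate adaptation
#'
#' Integrates the full network with the first-order Euler-Maruyama scheme in
#' compiled code. The state is initialised at the theoretical bump
#' (`U = bump_profile()`, `V = m * U`); when `m > 0` the adaptation bump is
#' shifted back by one grid point so that the direction of intrinsic motion
#' is broken deterministically rather than left to floating-point noise. A
#' burn-in period is simulated and discarded before recording starts.
#'
#' @param params A [can_params()] object.
#' @param duration Recorded duration in ms.
#' @param mode External input: `"none"` (replay), `"location"` (moving
#'   sensory bump; requires `beta > 0`), or `"gamma"` (uniform oscillation).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param record_every Record a snapshot every this many Euler steps
#'   (default: every 2 ms worth of steps).
#' @param burn_in Burn-in duration in ms, discarded (default 200).
#' @param init_centre Initial bump centre (m).
#' @param record_state If `TRUE`, keep full `U`, `V`, `r` snapshots (matrices
#'   time x neurons) in the result; otherwise only the decoded trajectory and
#'   population activity are kept.
#' @return An object of class `can_sim`: a list with `trajectory` (a tibble
#'   with columns `time`, `z`, `activity`), `params`, `mode`, `seed`, and,
#'   when `record_state = TRUE`, matrices `U_t`, `V_t`, `r_t`.
#' @examples
#' sim <- simulate_can(can_params(m = 0.07), duration = 500, seed = 1)
#' head(sim$trajectory)
#' @export
simulate_can <- function(params, duration, mode = c("none", "location", "gamma"),
                         seed = NULL, record_every = max(1L, round(2 / params$dt)),
                         burn_in = 200, init_centre = params$L / 2,
                         record_state = FALSE) {
  mode <- match.arg(mode)
  if (!bump_exists(params)) {
    stop("no bump solution for these parameters; see bump_exists()",
         call. = FALSE)
  }
  if (mode == "location" && params$beta <= 0) {
    stop("mode = \"location\" requires beta > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  xs <- neuron_positions(params)
  dx <- params$L / params$N
  J <- build_connectivity(params)
  U0 <- bump_profile(params, centre = init_centre)
  V0 <- params$m * U0
  if (params$m > 0) {
    # break the symmetric (unstable) equilibrium deterministically
    V0 <- params$m * U0[c(params$N, seq_len(params$N - 1L))]
  }
  mode_code <- match(mode, c("none", "location", "gamma")) - 1L
  n_burn <- round(burn_in / params$dt)
  t0 <- 0
  if (n_burn > 0) {
    burn <- can_simulate_cpp(U0, V0, J, xs, params$rho, dx, params$k,
                             params$tau_u, params$tau_v, params$m,
                             params$sigma_U, params$sigma_m, params$dt,
                             n_burn, n_burn, FALSE, mode_code,
                             params$beta, params$v_ext, params$a, params$L,
                             params$A_gamma, params$omega_gamma,
                             params$phi_gamma, t0)
    U0 <- burn$U_final
    V0 <- burn$V_final
    t0 <- burn_in
  }
  n_steps <- round(duration / params$dt)
  res <- can_simulate_cpp(U0, V0, J, xs, params$rho, dx, params$k,
                          params$tau_u, params$tau_v, params$m,
                          params$sigma_U, params$sigma_m, params$dt,
                          n_steps, record_every, record_state, mode_code,
                          params$beta, params$v_ext, params$a, params$L,
                          params$A_gamma, params$omega_gamma,
                          params$phi_gamma, t0)
  traj <- tibble::tibble(time = as.numeric(res$times), z = as.numeric(res$z),
                         activity = as.numeric(res$activity))
  out <- list(trajectory = traj, params = params, mode = mode, seed = seed,
              U_final = res$U_final, V_final = res$V_final)
  if (record_state) {
    out$U_t <- res$U_t
    out$V_t <- res$V_t
    out$r_t <- res$r_t
  }
  structure(out, class = "can_sim")
}

#' @export
print.can_sim <- function(x, ...) {
  cat(sprintf("<can_sim> mode = %s, %d snapshots, t in [%g, %g] ms\n",
              x$mode, nrow(x$trajectory), min(x$trajectory$time),
              max(x$trajectory$time)))
  cat(sprintf("  m = %g, gamma = %g, seed = %s\n", x$params$m, x$params$gamma,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Extract the decoded bump trajectory of a simulation
#'
#' @param sim A `can_sim` object.
#' @param label Optional condition label stored with the trajectory.
#' @return A `can_trajectory` tibble (columns `time`, `z`) with attributes
#'   `ring_length` and `label`, as consumed by the trajectory statistics.
#' @export
as_trajectory <- function(sim, label = sim$mode) {
  new_trajectory(sim$trajectory$time, sim$trajectory$z,
                 ring_length = sim$params$L, label = label)
}

#' Sample Poisson spike counts from rate snapshots
#'
#' Independent Poisson draws with mean `gain * rate * dt_bin` per neuron per
#' time bin, emulating spiking readout of the population rates.
#'
#' @param r_t Rate snapshot matrix (time bins x neurons), nonnegative.
#' @param dt_bin Bin width in ms.
#' @param gain Rate-to-intensity gain (must be nonnegative).
#' @param seed Optional integer seed.
#' @return Integer matrix of spike counts, same shape as `r_t`.
#' @export
sample_poisson_spikes <- function(r_t, dt_bin, gain = 50, seed = NULL) {
  if (gain < 0) stop("`gain` must be nonnegative", call. = FALSE)
  if (any(r_t < 0)) stop("rates must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(r_t), lambda = gain * as.numeric(r_t) * dt_bin)
  matrix(counts, nrow = nrow(r_t), ncol = ncol(r_t))
}
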