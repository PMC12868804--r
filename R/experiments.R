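#' Theta-sweep length versus replay diffusivity across networks
#'
#' For each simulated network an adaptation strength is drawn uniformly from
#' `m_range`; the network is run once in theta mode (moving location input,
#' `beta = 0.01`, `v_ext = 1.5` m/s) to obtain the mean theta-sweep length,
#' and once in replay mode (`beta = 0`) to obtain the diffusion exponent of
#' the spontaneous bump trajectory. The Pearson correlation between the two
#' quantities across networks quantifies how adaptation strength jointly
#' modulates replay diffusivity and theta-sweep amplitude.
#'
#' @param n_networks Number of networks (default 40).
#' @param m_range Range of adaptation strengths (default `c(0.04, 0.08)`).
#' @param gamma Normalised adaptation-noise level (default 0.1).
#' @param seed Master seed; per-network seeds are derived from it.
#' @param theta_duration,replay_duration Run durations in ms.
#' @param max_lag Lag cap for the diffusion-exponent fit.
#' @return List with `table` (tibble: `network`, `m`, `sweep_length`, `eta`),
#'   `r`, `p`, `n_failed` (networks dropped because a fit failed).
#' @export
run_theta_replay_correlation <- function(n_networks = 40,
                                         m_range = c(0.04, 0.08),
                                         gamma = 0.1, seed = 1,
                                         theta_duration = 3000,
                                         replay_duration = 10000,
                                         max_lag = 50) {
  set.seed(seed)
  ms <- stats::runif(n_networks, m_range[1], m_range[2])
  seeds <- sample.int(.Machine$integer.max %/% 2, n_networks)
  rows <- purrr::map(seq_len(n_networks), function(i) {
    p_theta <- can_params(m = ms[i], gamma = gamma, beta = 0.01, v_ext = 1.5)
    p_replay <- can_params(m = ms[i], gamma = gamma, beta = 0)
    out <- tryCatch({
      sim_t <- simulate_can(p_theta, theta_duration, mode = "location",
                            seed = seeds[i], init_centre = 0)
      actual <- new_trajectory(sim_t$trajectory$time,
                               (p_theta$v_ext / 1000) * sim_t$trajectory$time,
                               ring_length = p_theta$L, label = "actual")
      sweep <- theta_sweep_length(as_trajectory(sim_t), actual)
      sim_r <- simulate_can(p_replay, replay_duration, mode = "none",
                            seed = seeds[i] + 1L)
      eta <- diffusion_exponent(as_trajectory(sim_r), max_lag = max_lag)$eta
      tibble::tibble(network = i, m = ms[i], sweep_length = sweep, eta = eta)
    }, error = function(e) NULL)
    out
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  tab <- dplyr::bind_rows(rows)
  ct <- stats::cor.test(tab$eta, tab$sweep_length)
  list(table = tab, r = unname(ct$estimate), p = ct$p.value,
       n_failed = failed)
}

#' Pooled correlation between population activity and replay step size
#'
#' Runs replay-mode networks across several adaptation strengths, samples
#' Poisson spike counts from the population rate (summed across neurons per
#' window), computes per-window step sizes of the decoded trajectory, pools
#' all windows, and correlates summed counts with step size.
#'
#' The anticorrelation is real but small at spike-count resolution: the
#' population rate falls by only ~0.5% across the adaptation range while
#' step sizes grow several-fold, so Poisson sampling noise dominates single
#' windows and tens of thousands of pooled windows are needed before the
#' sign of the correlation is resolved. The default duration is sized
#' accordingly.
#'
#' @param m_values Adaptation strengths of the pooled runs.
#' @param gamma Normalised adaptation-noise level (default 0.6).
#' @param duration Per-run duration in ms (default 80000).
#' @param window_ms Step-size / spike-count window in ms (default 20).
#' @param gain Poisson rate gain (default 50; yields tens of counts per
#'   window with the default network).
#' @param seed Master seed.
#' @return List with `table` (tibble: `m`, `window`, `summed_spikes`,
#'   `step_size`), `r`, `p`, and the binned summary from
#'   [activity_step_correlation()].
#' @export
run_activity_step_experiment <- function(m_values = c(0.008, 0.012, 0.016, 0.019),
                                         gamma = 0.6, duration = 80000,
                                         window_ms = 20, gain = 50,
                                         seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, length(m_values))
  rows <- purrr::map2(m_values, seeds, function(m, sd_i) {
    p <- can_params(m = m, gamma = gamma)
    sim <- simulate_can(p, duration, mode = "none", seed = sd_i)
    tr <- sim$trajectory
    dt_rec <- tr$time[2] - tr$time[1]
    per_win <- round(window_ms / dt_rec)
    n_win <- floor((nrow(tr) - 1) / per_win)
    idx0 <- (seq_len(n_win) - 1) * per_win + 1
    steps <- ring_distance(tr$z[idx0 + per_win], tr$z[idx0], p$L)
    # population rate summed over neurons, averaged within the window
    sum_rate <- tr$activity / (p$L / p$N)
    win_rate <- vapply(idx0, function(i) mean(sum_rate[i:(i + per_win - 1)]),
                       numeric(1))
    counts <- stats::rpois(n_win, lambda = gain * win_rate * window_ms)
    tibble::tibble(m = m, window = seq_len(n_win),
                   summed_spikes = counts, step_size = steps)
  })
  tab <- dplyr::bind_rows(rows)
  res <- activity_step_correlation(tab$summed_spikes, tab$step_size)
  list(table = tab, r = res$r, p = res$p, binned = res$binned)
}

#' Replay diffusivity contrast between two adaptation strengths
#'
#' Runs matched replay simulations at a higher and a lower adaptation
#' strength over paired seeds and fits the diffusion exponent for each; with
#' both strengths above the motion boundary and equal noise, the higher-`m`
#' condition yields the larger exponent in most pairs.
#'
#' @param m_high,m_low The two adaptation strengths.
#' @param gamma Noise level for both (default 0.1).
#' @param n_pairs Number of matched seed pairs (default 10).
#' @param duration Per-run duration in ms (default 5000).
#' @param seed Master seed.
#' @return List with `table` (tibble: `pair`, `eta_high`, `eta_low`),
#'   `mean_eta_high`, `mean_eta_low`, `prop_high_greater`.
#' @export
run_state_diffusivity_contrast <- function(m_high = 0.019, m_low = 0.008,
                                           gamma = 0.6, n_pairs = 10,
                                           duration = 5000, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_pairs)
  tab <- purrr::map(seq_len(n_pairs), function(i) {
    eh <- diffusion_exponent(as_trajectory(
      simulate_can(can_params(m = m_high, gamma = gamma), duration,
                   seed = seeds[i])))$eta
    el <- diffusion_exponent(as_trajectory(
      simulate_can(can_params(m = m_low, gamma = gamma), duration,
                   seed = seeds[i])))$eta
    tibble::tibble(pair = i, eta_high = eh, eta_low = el)
  }) |> dplyr::bind_rows()
  list(table = tab,
       mean_eta_high = mean(tab$eta_high),
       mean_eta_low = mean(tab$eta_low),
       prop_high_greater = mean(tab$eta_high > tab$eta_low))
}

#' Classify the replay regime of a simulated trajectory
#'
#' A trajectory whose bump never strays more than one interaction range from
#' its start is `"stationary"`; otherwise the diffusion exponent decides:
#' `"diffusive"` within the Brownian band (`eta` in `[eta_band[1],
#' eta_band[2]]` or below) and `"superdiffusive"` above it.
#'
#' The exponent is fitted over lags of `bin_ms` to `bin_ms * max_lag`
#' milliseconds. The reduced position dynamics are a second-order process
#' whose displacement mode decorrelates over `tau_v / mu` (tens to hundreds
#' of ms), so lags must extend well beyond that crossover for the asymptotic
#' exponent to be visible; the 100-ms default assumes runs of a minute or
#' more.
#'
#' @param traj A ring trajectory (from [as_trajectory()]).
#' @param a Interaction range used as the stationarity scale (m).
#' @param eta_band Brownian band for the exponent (default `c(0.35, 0.62)`).
#' @param bin_ms,max_lag Lag grid for [diffusion_exponent()] (defaults 100 ms
#'   and 20 lags).
#' @return A list with `regime` and `eta` (`NA` for stationary runs).
#' @export
classify_replay_regime <- function(traj, a = 0.4, eta_band = c(0.35, 0.62),
                                   bin_ms = 100, max_lag = 20) {
  L <- traj_L(traj)
  excursion <- max(traj_dist(traj$z, traj$z[1], L))
  if (excursion < a) {
    return(list(regime = "stationary", eta = NA_real_))
  }
  eta <- diffusion_exponent(traj, max_lag = max_lag, bin_ms = bin_ms)$eta
  regime <- if (eta > eta_band[2]) "superdiffusive" else "diffusive"
  list(regime = regime, eta = eta)
}

#' Phase-diagram table with simulation spot checks
#'
#' Evaluates the analytic phase diagram on a grid and, for a sparse set of
#' check points, verifies the regime label with a full network simulation
#' classified by [classify_replay_regime()].
#'
#' @param m_values,gamma_values Grid axes.
#' @param check_points Tibble with columns `m`, `gamma` of points to verify
#'   by simulation (default: none).
#' @param params Baseline [can_params()].
#' @param duration Simulation duration for check points (ms); defaults to a
#'   minute so that [classify_replay_regime()]'s long-lag exponent fit is
#'   well posed.
#' @param seed Seed for check-point simulations.
#' @return List with `diagram` (tibble from [phase_diagram()]) and `checks`
#'   (tibble: `m`, `gamma`, `regime_theory`, `regime_sim`, `eta`).
#' @export
run_phase_diagram_figure <- function(m_values, gamma_values,
                                     check_points = NULL,
                                     params = can_params(),
                                     duration = 60000, seed = 1) {
  pd <- phase_diagram(m_values, gamma_values, params)
  checks <- NULL
  if (!is.null(check_points)) {
    checks <- purrr::pmap(check_points, function(m, gamma, ...) {
      theory <- phase_diagram(m, gamma, params)$regime
      sim <- simulate_can(can_params(m = m, gamma = gamma), duration,
                          seed = seed)
      cls <- classify_replay_regime(as_trajectory(sim), a = params$a)
      tibble::tibble(m = m, gamma = gamma, regime_theory = theory,
                     regime_sim = cls$regime, eta = cls$eta)
    }) |> dplyr::bind_rows()
  }
  list(diagram = pd, checks = checks)
}
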