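#' Construct a trajectory table
#'
#' A tibble of decoded (or synthetic) positions over time, the common
#' currency of the trajectory statistics. Positions on a ring are wrapped to
#' `[0, L)`; an unbounded (linear-track) trajectory uses
#' `ring_length = Inf`, in which case all distances below are plain absolute
#' differences.
#'
#' @param times Monotone time stamps (ms).
#' @param positions Positions; wrapped into `[0, ring_length)` when finite.
#' @param ring_length Ring circumference `L` (m), or `Inf`.
#' @param label Free-text condition identifier.
#' @return A `can_trajectory` tibble with columns `time`, `z` and attributes
#'   `ring_length`, `label`.
#' @export
new_trajectory <- function(times, positions, ring_length = Inf, label = "") {
  stopifnot(length(times) == length(positions), !is.unsorted(times))
  z <- if (is.finite(ring_length)) positions %% ring_length else positions
  out <- tibble::tibble(time = as.numeric(times), z = as.numeric(z))
  attr(out, "ring_length") <- ring_length
  attr(out, "label") <- label
  class(out) <- c("can_trajectory", class(out))
  out
}

traj_L <- function(traj) {
  L <- attr(traj, "ring_length")
  if (is.null(L)) Inf else L
}

traj_dist <- function(x, y, L) {
  if (is.finite(L)) ring_distance(x, y, L) else abs(x - y)
}

#' Step sizes of a trajectory at a given lag
#'
#' Circular distances `|z(t + lag) - z(t)|` (wrapped to at most `L/2` on a
#' ring) between positions separated by `lag_bins` sampling bins. If the
#' trajectory is sampled finer than `bin_ms` it is decimated to the `bin_ms`
#' grid first (the sampling interval must divide `bin_ms`).
#'
#' @param traj A trajectory tibble (columns `time`, `z`), e.g. from
#'   [new_trajectory()] or [as_trajectory()].
#' @param lag_bins Lag in units of `bin_ms` bins (default 1).
#' @param bin_ms Step-size sampling bin in ms (default 2).
#' @return Numeric vector of distances (empty, with a warning, when the
#'   trajectory is shorter than the lag).
#' @export
step_sizes <- function(traj, lag_bins = 1L, bin_ms = 2) {
  L <- traj_L(traj)
  z <- traj$z
  if (nrow(traj) > 1) {
    dt <- traj$time[2] - traj$time[1]
    if (abs(dt - bin_ms) > 1e-9) {
      stride <- bin_ms / dt
      if (abs(stride - round(stride)) > 1e-6 || stride < 1) {
        stop("sampling interval ", dt, " ms does not divide bin_ms = ",
             bin_ms, call. = FALSE)
      }
      z <- z[seq(1, length(z), by = round(stride))]
    }
  }
  n <- length(z)
  if (n <= lag_bins) {
    warning("trajectory shorter than requested lag; no step sizes")
    return(numeric(0))
  }
  traj_dist(z[seq_len(n - lag_bins) + lag_bins], z[seq_len(n - lag_bins)], L)
}

#' Diffusion exponent by log-log distance-lag regression
#'
#' For each lag multiple `j`, pools the distances between all position pairs
#' separated by `j` bins across all trajectories, takes the mean distance
#' `dbar(j)`, and fits `log(dbar)` against `log(j)` by least squares. The
#' slope is the diffusion exponent `eta` (0.5 for Brownian motion, 1 for
#' ballistic motion, above 0.5 for superdiffusion) and `exp(intercept)` the
#' scale constant `G`.
#'
#' @param trajs A trajectory tibble or a list of them.
#' @param max_lag Largest lag multiple; capped at `floor(n/4)` of the
#'   shortest trajectory (default 50).
#' @param bin_ms Step-size sampling bin in ms (default 2).
#' @return An object of class `diffusion_fit` with fields `eta`, `G`,
#'   `lags`, `mean_dist`, `r2`, `n`.
#' @examples
#' set.seed(1)
#' brown <- make_fixture(fixture_spec("brownian", n = 20, length = 300))
#' fit <- diffusion_exponent(brown)
#' fit$eta  # close to 0.5
#' @export
diffusion_exponent <- function(trajs, max_lag = 50, bin_ms = 2) {
  if (inherits(trajs, "can_trajectory") || (is.data.frame(trajs))) {
    trajs <- list(trajs)
  }
  stopifnot(length(trajs) >= 1)
  steps_by_traj <- lapply(trajs, function(tr) {
    n <- nrow(tr)
    cap <- min(max_lag, floor(n / 4))
    lapply(seq_len(max(cap, 0)), function(j) step_sizes(tr, j, bin_ms))
  })
  n_lags <- max(vapply(steps_by_traj, length, integer(1)))
  mean_dist <- vapply(seq_len(n_lags), function(j) {
    v <- unlist(lapply(steps_by_traj, function(s) if (j <= length(s)) s[[j]]))
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  lags <- seq_len(n_lags)
  ok <- is.finite(mean_dist) & mean_dist > 0
  if (sum(ok) < 5) {
    stop("fewer than 5 usable lags; cannot fit a diffusion exponent",
         call. = FALSE)
  }
  fit <- stats::lm(log(mean_dist[ok]) ~ log(lags[ok]))
  structure(list(eta = unname(stats::coef(fit)[2]),
                 G = unname(exp(stats::coef(fit)[1])),
                 lags = lags[ok], mean_dist = mean_dist[ok],
                 r2 = summary(fit)$r.squared,
                 n = length(trajs)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> eta = %.3f, G = %.4g, r2 = %.3f (%d lags, %d trajectories)\n",
              x$eta, x$G, x$r2, length(x$lags), x$n))
  invisible(x)
}

#' Power-law tail exponent of step sizes (continuous MLE)
#'
#' Hill-type maximum-likelihood estimate of the tail exponent of
#' `p(x) ~ x^(-1-alpha)` for steps above a quantile cutoff:
#' `alpha_hat = n_tail / sum(log(x_i / xmin))`.
#'
#' @param steps Positive step sizes.
#' @param xmin_quantile Quantile defining the lower cutoff (default 0.9).
#' @param xmin Optional explicit cutoff, overriding the quantile.
#' @return An object of class `powerlaw_fit` with `alpha_hat`, `xmin`,
#'   `n_tail`.
#' @export
powerlaw_tail_fit <- function(steps, xmin_quantile = 0.9, xmin = NULL) {
  steps <- steps[is.finite(steps) & steps > 0]
  if (is.null(xmin)) xmin <- stats::quantile(steps, xmin_quantile, names = FALSE)
  tail <- steps[steps >= xmin]
  if (length(tail) < 50) {
    stop("insufficient tail: only ", length(tail),
         " points above the cutoff (need >= 50)", call. = FALSE)
  }
  alpha <- length(tail) / sum(log(tail / xmin))
  structure(list(alpha_hat = alpha, xmin = xmin, n_tail = length(tail)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha_hat = %.3f (xmin = %.4g, n_tail = %d)\n",
              x$alpha_hat, x$xmin, x$n_tail))
  invisible(x)
}

#' Mean theta-sweep length of a decoded trajectory
#'
#' The signed wrapped offset between the decoded and the actual position is
#' segmented into cycles at the ascending crossings of its mean level; each
#' cycle's sweep length is the maximal look-ahead offset plus the magnitude
#' of the maximal look-back offset (both measured relative to the actual
#' position, with absent excursions contributing 0), and the mean over
#' complete cycles is returned. A decoded trajectory identical to the actual
#' one has sweep length 0.
#'
#' For an offset oscillating symmetrically about zero, segmenting at the
#' mean level coincides with segmenting at zero. Centring keeps the cycle
#' segmentation well defined when the oscillation rides on a steady lead —
#' the typical situation for an adaptation-driven bump tracking a moving
#' input, which anticipates the input and oscillates about a forward-shifted
#' equilibrium.
#'
#' @param decoded,actual Trajectory tibbles with aligned time stamps; the
#'   ring length is taken from `decoded`.
#' @return Mean sweep length (m).
#' @export
theta_sweep_length <- function(decoded, actual) {
  stopifnot(nrow(decoded) == nrow(actual))
  if (max(abs(decoded$time - actual$time)) > 1e-6) {
    stop("decoded and actual trajectories must share time stamps",
         call. = FALSE)
  }
  L <- traj_L(decoded)
  if (!is.finite(L)) stop("theta sweeps require a ring trajectory",
                          call. = FALSE)
  off <- ring_diff(decoded$z, actual$z, L)
  if (max(abs(off)) < 1e-9) return(0)
  ctr <- off - mean(off)
  up <- which(ctr[-length(ctr)] < 0 & ctr[-1] >= 0)
  if (length(up) < 4) {
    stop("fewer than 3 complete sweep cycles detected", call. = FALSE)
  }
  sweeps <- vapply(seq_len(length(up) - 1), function(i) {
    seg <- off[(up[i] + 1):up[i + 1]]
    max(seg, 0) + max(-seg, 0)
  }, numeric(1))
  mean(sweeps)
}

#' Correlation between population activity and step size
#'
#' Pearson correlation between per-window summed spike counts and the step
#' size of the decoded trajectory in the same window, plus a binned summary
#' (mean counts per step-size bin).
#'
#' @param spike_counts Summed spike counts per window.
#' @param steps Step sizes per window (same length, >= 10).
#' @param n_bins Number of step-size bins for the summary (default 6).
#' @return List with `r`, `p`, `n` and `binned` (tibble with `step_mid`,
#'   `mean_counts`, `n`).
#' @export
activity_step_correlation <- function(spike_counts, steps, n_bins = 6) {
  stopifnot(length(spike_counts) == length(steps))
  if (length(steps) < 10) stop("need at least 10 windows", call. = FALSE)
  if (stats::sd(spike_counts) == 0 || stats::sd(steps) == 0) {
    stop("undefined correlation: zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(spike_counts, steps)
  brks <- stats::quantile(steps, probs = seq(0, 1, length.out = n_bins + 1))
  brks <- unique(brks)
  bin <- cut(steps, brks, include.lowest = TRUE)
  binned <- tibble::tibble(counts = spike_counts, step = steps, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(step_mid = stats::median(.data$step),
                     mean_counts = mean(.data$counts),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::select("step_mid", "mean_counts", "n")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(steps),
       binned = binned)
}

#' Phase profile of a signal against an oscillation
#'
#' Bins a time series by the instantaneous phase of an oscillation, returns
#' per-bin means, and the circular weighted mean phase of the mean-centred
#' values (`angle of sum((v - mean(v)) * exp(1i*phase))`), with resultant
#' length normalised by the summed absolute weights. Empty bins are linearly
#' interpolated from their neighbours with a warning.
#'
#' @param values Signal values (aligned with `phases`).
#' @param phases Oscillation phases in radians (wrapped into `[0, 2*pi)`).
#' @param n_bins Number of phase bins (>= 8; default 16).
#' @return An object of class `phase_profile` with `phase_bins` (centres),
#'   `mean_value`, `circ_mean` (in `[0, 2*pi)`), `circ_r`.
#' @export
phase_profile <- function(values, phases, n_bins = 16) {
  stopifnot(length(values) == length(phases), n_bins >= 8)
  ph <- phases %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  idx <- findInterval(ph, edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  mv <- vapply(seq_len(n_bins), function(b) {
    v <- values[idx == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (anyNA(mv)) {
    warning("empty phase bins interpolated")
    mv <- stats::approx(which(!is.na(mv)), mv[!is.na(mv)],
                        xout = seq_len(n_bins), rule = 2)$y
  }
  w <- values - mean(values)
  resultant <- sum(w * exp(1i * ph))
  circ_r <- if (sum(abs(w)) > 0) Mod(resultant) / sum(abs(w)) else 0
  structure(list(phase_bins = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 mean_value = mv,
                 circ_mean = Arg(resultant) %% (2 * pi),
                 circ_r = circ_r),
            class = "phase_profile")
}

#' Place-field size index by population vector correlation
#'
#' Correlates the population rate vector between every pair of spatial bins,
#' averages the correlation matrix along each diagonal offset, smooths the
#' resulting decay curve with a Gaussian kernel, and returns the slope from
#' the curve's peak to its trough. A larger index means faster spatial
#' decorrelation, i.e. smaller place fields.
#'
#' @param rates Rate matrix, units x spatial bins (nonnegative). Constant
#'   rows (undefined correlation) are dropped with a warning.
#' @param smooth_sigma Gaussian smoothing width in bins (default 5).
#' @return List with `index`, `curve` (tibble `offset`, `pvc`,
#'   `pvc_smooth`) and `n_units`.
#' @export
pvc_place_field_index <- function(rates, smooth_sigma = 5) {
  stopifnot(is.matrix(rates), ncol(rates) >= 10)
  keep <- apply(rates, 1, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant unit row(s) dropped")
    rates <- rates[keep, , drop = FALSE]
  }
  if (nrow(rates) < 2) stop("need at least 2 non-constant units",
                            call. = FALSE)
  C <- stats::cor(rates)  # bins x bins, population vectors over units
  l <- ncol(C)
  pvc <- vapply(0:(l - 1), function(d) {
    mean(C[cbind(seq_len(l - d), seq_len(l - d) + d)])
  }, numeric(1))
  # Gaussian smoothing with edge-renormalised kernel
  half <- max(1L, ceiling(3 * smooth_sigma))
  kern <- stats::dnorm(-half:half, sd = smooth_sigma)
  sm <- vapply(seq_along(pvc), function(i) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= length(pvc)
    sum(pvc[j[ok]] * kern[ok]) / sum(kern[ok])
  }, numeric(1))
  ipk <- which.max(sm)
  itr <- ipk - 1L + which.min(sm[ipk:length(sm)])
  index <- if (itr > ipk) (sm[ipk] - sm[itr]) / (itr - ipk) else 0
  list(index = index,
       curve = tibble::tibble(offset = 0:(l - 1), pvc = pvc, pvc_smooth = sm),
       n_units = nrow(rates))
}
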