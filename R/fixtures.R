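#' Specification of a synthetic fixture
#'
#' Deterministic-given-seed generators for the synthetic inputs used to
#' calibrate and test the trajectory estimators: Brownian and ballistic
#' position series, Levy walks with Pareto flight lengths, bare Pareto step
#' draws, and Gaussian tuning-curve rate maps on a linear track.
#'
#' @param kind One of `"brownian"`, `"ballistic"`, `"levy"`,
#'   `"pareto_steps"`, `"rate_map"`.
#' @param n Number of trajectories / draws / units.
#' @param length Number of steps per trajectory (or spatial bins for
#'   `"rate_map"`).
#' @param seed Integer seed.
#' @param step_sigma Brownian increment standard deviation.
#' @param speed Ballistic / Levy-walk speed (length units per bin).
#' @param tail_exponent Pareto tail exponent `alpha` (for `"levy"` and
#'   `"pareto_steps"`).
#' @param xmin Pareto scale (minimum flight length / step).
#' @param tuning_width Tuning-curve width for `"rate_map"` (in bins).
#' @param bin_ms Sampling bin in ms for trajectory kinds.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("brownian", "ballistic", "levy",
                                  "pareto_steps", "rate_map"),
                         n = 200, length = 500, seed = 1,
                         step_sigma = 1, speed = 1,
                         tail_exponent = 1.5, xmin = 1,
                         tuning_width = 5, bin_ms = 2) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n = n, length = length, seed = seed,
                 step_sigma = step_sigma, speed = speed,
                 tail_exponent = tail_exponent, xmin = xmin,
                 tuning_width = tuning_width, bin_ms = bin_ms),
            class = "fixture_spec")
}

rpareto <- function(n, alpha, xmin) xmin * stats::runif(n)^(-1 / alpha)

#' Generate a synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @return For trajectory kinds, a list of [new_trajectory()] tibbles
#'   (`ring_length = Inf`); for `"pareto_steps"`, a numeric vector; for
#'   `"rate_map"`, a units x bins matrix of Gaussian tuning curves with
#'   evenly tiled centres on a linear track.
#' @examples
#' trajs <- make_fixture(fixture_spec("ballistic", n = 3, length = 100))
#' diffusion_exponent(trajs)$eta  # 1: distance grows linearly with lag
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  times <- (0:spec$length) * spec$bin_ms
  switch(spec$kind,
    brownian = lapply(seq_len(spec$n), function(i) {
      z <- cumsum(c(0, stats::rnorm(spec$length, sd = spec$step_sigma)))
      new_trajectory(times, z, label = "brownian")
    }),
    ballistic = lapply(seq_len(spec$n), function(i) {
      new_trajectory(times, spec$speed * (0:spec$length), label = "ballistic")
    }),
    levy = lapply(seq_len(spec$n), function(i) {
      # Levy walk: Pareto flight lengths traversed at constant speed with
      # random direction; the position series is read off on the bin grid.
      z <- numeric(spec$length + 1)
      pos <- 0
      step <- 1
      while (step <= spec$length) {
        flight <- rpareto(1, spec$tail_exponent, spec$xmin)
        dir <- sample(c(-1, 1), 1)
        dur <- max(1L, round(flight / spec$speed))
        take <- min(dur, spec$length - step + 1)
        z[step + seq_len(take)] <- pos + dir * spec$speed * seq_len(take)
        pos <- z[step + take]
        step <- step + take
      }
      new_trajectory(times, z, label = "levy")
    }),
    pareto_steps = rpareto(spec$n, spec$tail_exponent, spec$xmin),
    rate_map = {
      centres <- seq(0, spec$length, length.out = spec$n + 1)[-(spec$n + 1)]
      bins <- 0:(spec$length - 1)
      t(vapply(centres, function(c0) {
        exp(-(bins - c0)^2 / (2 * spec$tuning_width^2))
      }, numeric(spec$length)))
    })
}
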