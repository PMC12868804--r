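test_that("new_trajectory wraps ring positions and keeps attributes", {
  tr <- new_trajectory(c(0, 2, 4), c(-0.1, 6.5, 3.0), ring_length = 6.4,
                       label = "demo")
  expect_s3_class(tr, "can_trajectory")
  expect_equal(tr$z, c(6.3, 0.1, 3.0))
  expect_equal(attr(tr, "ring_length"), 6.4)
  expect_equal(attr(tr, "label"), "demo")
  lin <- new_trajectory(c(0, 1), c(-5, 10))
  expect_equal(lin$z, c(-5, 10))
  expect_error(new_trajectory(c(2, 1), c(0, 0)), "unsorted")
})

test_that("step_sizes wraps across the ring seam and decimates", {
  tr <- new_trajectory(seq(0, 8, by = 2), c(6.3, 0.1, 0.3, 6.2, 3.0),
                       ring_length = 6.4)
  expect_equal(step_sizes(tr), c(0.2, 0.2, 0.5, 3.2))
  # finer sampling is decimated onto the bin grid
  fine <- new_trajectory(seq(0, 8, by = 1), seq(0, 8, by = 1) * 0.1,
                         ring_length = 6.4)
  expect_equal(step_sizes(fine, bin_ms = 2), rep(0.2, 4))
  expect_error(step_sizes(fine, bin_ms = 1.5), "does not divide")
  short <- new_trajectory(0, 1, ring_length = 6.4)
  expect_warning(out <- step_sizes(short), "shorter")
  expect_length(out, 0)
})

test_that("diffusion exponent calibrates on canonical fixtures", {
  brown <- make_fixture(fixture_spec("brownian", n = 100, length = 500))
  expect_equal(diffusion_exponent(brown)$eta, 0.5, tolerance = 0.05)
  ball <- make_fixture(fixture_spec("ballistic", n = 3, length = 200))
  # the exactly linear log-log relation triggers lm's perfect-fit warning
  fit_b <- suppressWarnings(diffusion_exponent(ball))
  expect_equal(fit_b$eta, 1, tolerance = 1e-8)
  expect_gt(fit_b$r2, 0.999)
  levy <- make_fixture(fixture_spec("levy", n = 100, length = 500,
                                    tail_exponent = 1.2))
  expect_gt(diffusion_exponent(levy)$eta, 0.62)
  tiny <- new_trajectory(seq(0, 10, 2), rnorm(6), ring_length = 6.4)
  expect_error(suppressWarnings(diffusion_exponent(tiny)), "fewer than 5")
})

test_that("Hill estimator recovers Pareto tail exponents", {
  s15 <- make_fixture(fixture_spec("pareto_steps", n = 20000,
                                   tail_exponent = 1.5))
  expect_equal(powerlaw_tail_fit(s15)$alpha, 1.5, tolerance = 0.1)
  s25 <- make_fixture(fixture_spec("pareto_steps", n = 20000, seed = 2,
                                   tail_exponent = 2.5))
  expect_equal(powerlaw_tail_fit(s25)$alpha, 2.5, tolerance = 0.15)
  fit <- powerlaw_tail_fit(s15, xmin = 1)  # explicit cutoff: whole sample
  expect_equal(fit$n_tail, 20000)
  expect_error(powerlaw_tail_fit(s15[1:100]), "insufficient tail")
})

test_that("theta sweep length matches oracles and validates input", {
  t <- seq(0, 1000, by = 2)
  actual <- new_trajectory(t, rep(3, length(t)), ring_length = 6.4)
  expect_equal(theta_sweep_length(actual, actual), 0)
  # pure oscillation of amplitude A sweeps 2A per cycle
  dec <- new_trajectory(t, 3 + 0.5 * sin(2 * pi * t / 100), ring_length = 6.4)
  expect_equal(theta_sweep_length(dec, actual), 1, tolerance = 0.01)
  # oscillation riding on a steady forward lead: sweep spans the lead plus
  # the forward excursion, with no look-back component
  dec2 <- new_trajectory(t, 3 + 0.8 + 0.5 * sin(2 * pi * t / 100),
                         ring_length = 6.4)
  expect_equal(theta_sweep_length(dec2, actual), 1.3, tolerance = 0.01)
  lin <- new_trajectory(t, rep(3, length(t)))
  expect_error(theta_sweep_length(lin, lin), "ring")
  few <- new_trajectory(t, 3 + 0.5 * sin(2 * pi * t / 900), ring_length = 6.4)
  expect_error(theta_sweep_length(few, actual), "cycles")
  shifted <- new_trajectory(t + 1, rep(3, length(t)), ring_length = 6.4)
  expect_error(theta_sweep_length(actual, shifted), "time stamps")
})

test_that("stronger adaptation produces longer theta sweeps in the network", {
  sweep_for <- function(m) {
    p <- can_params(m = m, beta = 0.01, v_ext = 1.5)
    sim <- simulate_can(p, 3000, mode = "location", seed = 2, init_centre = 0)
    actual <- new_trajectory(sim$trajectory$time,
                             (p$v_ext / 1000) * sim$trajectory$time,
                             ring_length = p$L)
    theta_sweep_length(as_trajectory(sim), actual)
  }
  expect_gt(sweep_for(0.19), sweep_for(0.12))
})

test_that("activity-step correlation handles perfect and degenerate input", {
  steps <- seq(0.1, 2, length.out = 40)
  counts <- 100 - 30 * steps
  res <- activity_step_correlation(counts, steps)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_equal(res$n, 40)
  expect_true(all(diff(res$binned$mean_counts) < 0))
  expect_error(activity_step_correlation(rep(5, 40), steps), "zero-variance")
  expect_error(activity_step_correlation(1:5, 1:5), "at least 10")
})

test_that("phase profile recovers the preferred phase of a locked signal", {
  set.seed(1)
  ph <- runif(5000, 0, 2 * pi)
  pp <- phase_profile(2 + cos(ph - 1) + rnorm(5000, sd = 0.1), ph)
  expect_s3_class(pp, "phase_profile")
  expect_lt(abs(pp$circ_mean - 1), 0.1)
  expect_gt(pp$circ_r, 0.3)
  expect_equal(pp$phase_bins[which.max(pp$mean_value)], 1, tolerance = 0.25)
  # sparse phases leave empty bins, which are interpolated with a warning
  expect_warning(phase_profile(1:20, rep(c(0.1, 3), 10)), "empty phase bins")
})

test_that("PVC index reports faster decorrelation for narrower fields", {
  narrow <- make_fixture(fixture_spec("rate_map", n = 40, length = 200,
                                      tuning_width = 4))
  wide <- make_fixture(fixture_spec("rate_map", n = 40, length = 200,
                                    tuning_width = 16))
  i_n <- pvc_place_field_index(narrow)
  i_w <- pvc_place_field_index(wide)
  expect_gt(i_n$index, i_w$index)
  expect_equal(i_n$curve$pvc[1], 1)
  expect_equal(i_n$n_units, 40)
  bad <- rbind(narrow, 0 * narrow[1, , drop = FALSE])
  expect_warning(pvc_place_field_index(bad), "constant unit")
})
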