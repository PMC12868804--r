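test_that("reduce_params maps network parameters to (mu, gamma)", {
  rp_d <- reduce_params(can_params(m = 0.008, gamma = 0.6))
  expect_s3_class(rp_d, "reduced_params")
  expect_equal(rp_d$mu, 1 - 48 * 0.008)
  expect_equal(rp_d$gamma, 0.6)
  rp_s <- reduce_params(can_params(m = 0.019, gamma = 0.95))
  expect_equal(rp_s$mu, 0.088, tolerance = 1e-12)
  # the displacement scale combines synaptic and adaptation noise
  expect_gt(rp_d$sigma_s, sqrt(2) * 0.4 * 0.6)
  expect_equal(rp_d$Au_bar, bump_amplitude_theory(can_params())$Au)
})

test_that("alpha exponent matches the closed form and rejects gamma = 0", {
  expect_equal(alpha_exponent(0.616, 0.6), 1 + 2 * 0.616 / 0.36)
  expect_equal(alpha_exponent(0.088, 0.95), 1.195, tolerance = 1e-3)
  expect_equal(alpha_exponent(c(0.5, -0.1), c(1, 1)), c(2, 0.8))
  expect_error(alpha_exponent(0.5, 0), "gamma > 0")
})

test_that("stationary displacement density is normalised and symmetric", {
  rp <- reduce_params(can_params(m = 0.008, gamma = 0.6))
  dens <- stationary_s_density(rp)
  total <- stats::integrate(dens$pdf, dens$support[1], dens$support[2],
                            rel.tol = 1e-8, subdivisions = 1000L)$value
  expect_equal(total, 1, tolerance = 1e-4)
  s <- seq(0.01, 2, by = 0.07)
  expect_equal(dens$pdf(s), dens$pdf(-s))
  expect_true(all(diff(dens$pdf(s)) < 0))  # unimodal, peaked at 0
  # density vanishes outside the declared support
  expect_equal(dens$pdf(dens$support[2] * 1.01), 0)
  expect_error(stationary_s_density(reduce_params(can_params(m = 0.008))),
               "gamma > 0")
  # mu/gamma^2 <= -1/2 is non-normalisable
  expect_error(stationary_s_density(reduce_params(
    can_params(m = 0.05, gamma = 1))), "non-normalizable")
})

test_that("simulate_langevin is reproducible and tidy", {
  rp <- reduce_params(can_params(m = 0.008, gamma = 0.6, sigma_U = 5e-4))
  s1 <- simulate_langevin(rp, 100, seed = 1)
  s2 <- simulate_langevin(rp, 100, seed = 1)
  expect_identical(s1, s2)
  expect_s3_class(s1, "tbl_df")
  expect_named(s1, c("time", "z", "s"))
  expect_type(s1$z, "double")
  thin <- simulate_langevin(rp, 100, seed = 1, record_every = 10L)
  expect_equal(thin$z, s1$z[match(thin$time, s1$time)])
  expect_error(simulate_langevin(rp, 100, dt = 2), "dt")
})

test_that("Langevin displacement samples follow the stationary density", {
  rp <- reduce_params(can_params(m = 0.008, gamma = 0.6, sigma_U = 5e-4))
  sim <- simulate_langevin(rp, 1e6, seed = 1, record_every = 1000L)
  s <- sim$s[sim$time > 2000]  # drop transient; samples 100 ms apart
  dens <- stationary_s_density(rp)
  grid <- seq(-max(abs(s)) * 1.1, max(abs(s)) * 1.1, length.out = 20001)
  cdf_vals <- cumsum(dens$pdf(grid)) * diff(grid[1:2])
  cdf <- stats::approxfun(grid, cdf_vals / max(cdf_vals), rule = 2)
  ks <- max(abs(seq_along(s) / length(s) - cdf(sort(s))))
  expect_lt(ks, 0.05)
})

test_that("Langevin step sizes reproduce the predicted heavy tail", {
  rp <- reduce_params(can_params(m = 0.019, gamma = 0.95, sigma_U = 5e-4))
  sim <- simulate_langevin(rp, 1e6, seed = 1, record_every = 100L)
  steps <- abs(diff(sim$z))  # 10-ms steps
  fit <- powerlaw_tail_fit(steps)
  expect_equal(fit$alpha, alpha_exponent(rp$mu, rp$gamma), tolerance = 0.3)
})

test_that("network step-size tail matches the exponent map (diffusive row)", {
  p <- can_params(m = 0.008, gamma = 0.6, sigma_U = 5e-4)
  sim <- simulate_can(p, 2e5, seed = 5)
  steps <- step_sizes(as_trajectory(sim), bin_ms = 20)
  fit <- powerlaw_tail_fit(abs(steps))
  alpha_th <- alpha_exponent(1 - 48 * 0.008, 0.6)  # 4.42
  expect_equal(fit$alpha, alpha_th, tolerance = 0.5)
})

test_that("phase diagram classifies the canonical parameter rows", {
  pd <- phase_diagram(c(0.004, 0.008, 0.019, 0.05), c(0.05, 0.6, 0.95))
  expect_s3_class(pd, "tbl_df")
  expect_named(pd, c("m", "gamma", "mu", "alpha", "regime"))
  get <- function(m, g) pd[pd$m == m & pd$gamma == g, ]
  expect_equal(get(0.004, 0.05)$regime, "stationary")
  expect_equal(get(0.008, 0.6)$regime, "diffusive")
  expect_equal(get(0.008, 0.6)$alpha, 2)  # 4.42 clipped to 2
  expect_equal(get(0.019, 0.95)$regime, "superdiffusive")
  expect_equal(get(0.019, 0.95)$alpha, 1.195, tolerance = 1e-3)
  # deep supra-threshold: exponent non-positive, reported as NA
  expect_true(is.na(get(0.05, 0.6)$alpha))
  expect_equal(get(0.05, 0.6)$regime, "superdiffusive")
  expect_error(phase_diagram(0.008, -0.5), "gamma")
})

test_that("mode projections recover bump height and detect displacement", {
  p <- can_params()
  Au <- bump_amplitude_theory(p)$Au
  U <- bump_profile(p, centre = 3.2)
  pr <- project_modes(U, 3.2, p)
  expect_equal(pr$height, Au, tolerance = 1e-3)
  expect_lt(abs(pr$position), 1e-10)
  # displaced bump: position coefficient has the sign of the displacement
  expect_gt(project_modes(bump_profile(p, centre = 3.3), 3.2, p)$position, 0)
  expect_lt(project_modes(bump_profile(p, centre = 3.1), 3.2, p)$position, 0)
})
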