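test_that("connectivity is Gaussian, symmetric and translation invariant", {
  p <- can_params()
  J <- build_connectivity(p)
  expect_equal(dim(J), c(p$N, p$N))
  expect_equal(J, t(J))
  expect_equal(J[1, 1], p$J0 / (2 * pi * p$a^2))
  # circulant: every row is a rotation of the first
  expect_equal(J[2, 2], J[1, 1])
  expect_equal(J[1, 5], J[2, 6])
})

test_that("firing rate implements divisive global inhibition", {
  p <- can_params()
  U <- bump_profile(p) * 0.1
  r <- firing_rate(U, p)
  dx <- p$L / p$N
  denom <- 1 + p$k * p$rho * dx * sum(U^2)
  expect_equal(r, U^2 / denom)
  expect_true(all(r >= 0))
})

test_that("noise-free adaptation-free bump is a fixed point within 1%", {
  p <- can_params(m = 0, sigma_U = 0)
  sim <- simulate_can(p, 1000, seed = 1, record_state = TRUE)
  Au <- bump_amplitude_theory(p)$Au
  U_fin <- max(sim$U_final)
  expect_lt(abs(U_fin - Au) / Au, 0.01)
  # the bump does not drift
  z <- sim$trajectory$z
  expect_lt(max(ring_distance(z, z[1], p$L)), 1e-6)
})

test_that("drift threshold sits at m0 = tau_u/tau_v", {
  p <- can_params()
  m0 <- transition_boundary(p)
  v_low <- abs(measure_bump_speed(0.5 * m0, duration = 1000))
  v_high <- abs(measure_bump_speed(2 * m0, duration = 1500))
  expect_lt(v_low * 1000, 1e-4 * p$L)  # < 1e-4 ring lengths per second
  expect_gt(v_high, 1e-3)              # clearly travelling (m per ms)
})

test_that("noise-free speed is monotone in m and matches the corrected law", {
  p <- can_params()
  v <- vapply(c(0.03, 0.05, 0.07), measure_bump_speed, numeric(1))
  v <- abs(v)
  expect_true(all(diff(v) > 0))
  # simulation agrees with the sqrt(2)-corrected prefactor within 10%
  # (see the vignette for the analysis of the closed-form prefactor)
  v_corr <- intrinsic_speed(p, m = c(0.03, 0.05, 0.07)) / sqrt(2)
  expect_true(all(abs(v - v_corr) / v_corr < 0.10))
})

test_that("decoder is translation equivariant and exact on symmetric bumps", {
  p <- can_params()
  r <- firing_rate(bump_profile(p, centre = 3.2) * 0.1, p)
  expect_equal(decode_bump_centre(r, p), 3.2, tolerance = 1e-6)
  r_shift <- r[c(p$N, seq_len(p$N - 1L))]
  z1 <- decode_bump_centre(r, p)
  z2 <- decode_bump_centre(r_shift, p)
  expect_equal(ring_diff(z2, z1, p$L), p$L / p$N, tolerance = 1e-6)
})

test_that("R euler_step agrees with the compiled integrator", {
  p <- can_params(m = 0.03, sigma_U = 0, gamma = 0)
  J <- build_connectivity(p)
  U0 <- bump_profile(p) * 0.1
  V0 <- p$m * U0
  st <- list(U = U0, V = V0, r = firing_rate(U0, p), t = 0)
  for (i in 1:100) st <- euler_step(st, p, J)
  res <- canreplay:::can_simulate_cpp(
    U0, V0, J, neuron_positions(p), p$rho, p$L / p$N, p$k,
    p$tau_u, p$tau_v, p$m, 0, 0, p$dt, 100L, 100L, FALSE,
    0L, 0, 0, p$a, p$L, 0, 0, 0, 0)
  expect_equal(st$U, as.numeric(res$U_final), tolerance = 1e-12)
  expect_equal(st$V, as.numeric(res$V_final), tolerance = 1e-12)
})

test_that("simulate_can is reproducible and returns a tidy trajectory", {
  p <- can_params(m = 0.008, gamma = 0.6)
  s1 <- simulate_can(p, 500, seed = 7)
  s2 <- simulate_can(p, 500, seed = 7)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_s3_class(s1$trajectory, "tbl_df")
  expect_named(s1$trajectory, c("time", "z", "activity"))
  expect_type(s1$trajectory$z, "double")
  expect_true(all(s1$trajectory$z >= 0 & s1$trajectory$z < p$L))
  s3 <- simulate_can(p, 500, seed = 8)
  expect_false(identical(s1$trajectory$z, s3$trajectory$z))
})

test_that("location mode tracks a moving input", {
  p <- can_params(m = 0.05, beta = 0.01, v_ext = 1.5)
  sim <- simulate_can(p, 2000, mode = "location", seed = 2, init_centre = 0)
  tr <- sim$trajectory
  off <- ring_distance(tr$z, (p$v_ext / 1000) * tr$time, p$L)
  expect_lt(stats::median(off[tr$time > 500]), 0.2)
})

test_that("gamma mode modulates total activity at the drive harmonics", {
  p <- can_params(m = 0.008, gamma = 0.6)
  sim <- simulate_can(p, 5000, mode = "gamma", seed = 3)
  tr <- sim$trajectory
  act <- tr$activity - mean(tr$activity)
  f_drive <- p$omega_gamma / (2 * pi)  # Hz (time stamps are in ms)
  coef_at <- function(f) Mod(mean(act * exp(-2i * pi * f * tr$time / 1000)))
  off_band <- coef_at(2.7 * f_drive)
  # rectification through r = U^2 makes the strongest response the second
  # harmonic of the uniform sinusoidal drive; both harmonics stand clear of
  # the off-band floor
  expect_gt(coef_at(f_drive), 5 * off_band)
  expect_gt(coef_at(2 * f_drive), 20 * off_band)
})

test_that("record_state returns state matrices of the right shape", {
  p <- can_params(m = 0.03)
  sim <- simulate_can(p, 100, seed = 1, record_state = TRUE)
  n_rec <- nrow(sim$trajectory)
  expect_equal(dim(sim$U_t), c(n_rec, p$N))
  expect_equal(dim(sim$V_t), c(n_rec, p$N))
  expect_equal(dim(sim$r_t), c(n_rec, p$N))
  expect_true(all(sim$r_t >= 0))
})

test_that("Poisson spike sampling matches its rate law", {
  r_t <- matrix(c(0, 1, 2, 5), nrow = 2)
  expect_true(all(sample_poisson_spikes(r_t, dt_bin = 2, gain = 0,
                                        seed = 1) == 0))
  counts <- replicate(2000, sum(sample_poisson_spikes(
    matrix(2, 1, 1), dt_bin = 2, gain = 10)))
  expect_equal(mean(counts), 10 * 2 * 2, tolerance = 0.05)
  expect_error(sample_poisson_spikes(r_t, dt_bin = 2, gain = -1), "gain")
})
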