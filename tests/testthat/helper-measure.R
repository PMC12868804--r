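measure_bump_speed <- function(m, duration = 1500, window = 500) {
  p <- can_params(m = m, sigma_U = 0, gamma = 0)
  sim <- simulate_can(p, duration, seed = 1)
  tr <- sim$trajectory
  keep <- tr$time >= duration - window
  z <- tr$z[keep]
  t <- tr$time[keep]
  dz <- ring_diff(z[-1], z[-length(z)], p$L)
  sum(dz) / (t[length(t)] - t[1])  # m per ms, signed
}
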