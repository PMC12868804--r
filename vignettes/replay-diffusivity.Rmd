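---
title: "Replay diffusivity in an adapting attractor network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replay diffusivity in an adapting attractor network: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(canreplay)
```

This vignette documents the modelling choices, numerical conventions and
calibration analyses behind `canreplay`, including the places where the
full network deviates from its analytical reduction. Chunks are written to
be runnable but are not evaluated at build time; the long ones state their
approximate runtime.

## 1. Model and integration

The network is a ring of `N` rate neurons at density `rho` (circumference
`L = N / rho`), with Gaussian recurrent weights of range `a`, divisive
global inhibition of strength `k`, synaptic time constant `tau_u`, and an
adaptation variable `V` that low-pass filters `U` with gain `m` at time
constant `tau_v`. Integration is first-order Euler–Maruyama at `dt = 0.1`
ms in compiled code; `euler_step()` is a reference R implementation tested
to agree with the compiled path to `1e-12`.

Two conventions deserve a note:

* **Synaptic noise floor.** The additive noise `sigma_U` is not part of the
  core parameter set; it only sets the scale of sub-threshold bump wander.
  The package default is `sigma_U = 5e-4` (about 0.4% of the bump height),
  chosen so that the stationary row of the phase diagram stays stationary
  over one-minute runs while the diffusive row is measurably mobile. Tail
  exponent estimates below are robust to `sigma_U` over 5e-5–5e-4.

* **Initialisation.** Simulations start from the analytic bump profile with
  `V = m * U`. That configuration is an unstable equilibrium for
  `m > tau_u / tau_v`: floating-point symmetry would otherwise pick the
  travelling direction nondeterministically, so when `m > 0` the adaptation
  profile is shifted back by one grid point, seeding motion in a fixed
  direction deterministically.

## 2. Bump existence, amplitude and speed

`bump_amplitude_theory()` gives the fixed-point height `Au` from the
self-consistency condition; simulated noise-free bumps match it within 1%
(acceptance criterion 5b is green).

The closed-form intrinsic speed law (`intrinsic_speed()`) is
`v = (2a / tau_v) * sqrt(r - sqrt(r))` with `r = m * tau_v / tau_u`. The
simulated noise-free speed reproduces its *shape* — the threshold at
`m0 = tau_u / tau_v` and the square-root growth — but sits uniformly at
`1/sqrt(2)` of it:

```{r speed, eval = FALSE}
# ~10 s; measured ratios v_sim / v_formula at m = 0.03, 0.05, 0.07:
#   0.741, 0.764, 0.771  (1/sqrt(2) = 0.707)
# v_sim / (v_formula / sqrt(2)): 1.048, 1.081, 1.090
```

The deviation is m-independent to within 9%, strongly suggesting a constant
prefactor issue in the derivation of the closed form rather than a
simulation artefact (the integrator passes exact-agreement and fixed-point
tests; halving `dt` does not move the ratios). The package keeps the
documented closed form in `intrinsic_speed()` and records the discrepancy:
the acceptance test for the speed law at the 10% tolerance is deliberately
left red, and the unit suite instead pins the `sqrt(2)`-corrected law,
which holds within 10%.

## 3. Langevin reduction and its validity

`reduce_params()` maps network parameters to `(mu, gamma, sigma_s, a_z,
a_s)`; `simulate_langevin()` integrates the reduced system with the white
noises taken per unit of rescaled time (`t / tau_v` for the displacement,
`t / tau_u` for the position). Under that convention the stationary
displacement density of `stationary_s_density()` is the exact Fokker–Planck
solution; a 1000-s reduced simulation matches it with a Kolmogorov–Smirnov
statistic of 0.008 (test suite, criterion-level check).

The step-size tail exponent `alpha = 1 + 2 * mu / gamma^2` is recovered by
the Hill estimator on reduced-trajectory steps within 0.3 at `n = 1e5`
(acceptance criterion 5c, green).

**Where the reduction fails quantitatively.** The reduction linearises the
restoring force on the bump–adaptation separation. In the full network the
separation saturates (the adaptation bump cannot fall arbitrarily far
behind), so the instantaneous bump speed is bounded: network flights are
Lévy *walks* with truncated step-size tails rather than Lévy flights. In
the diffusive row (`m = 0.008`, `gamma = 0.6`) the measured network tail
exponent (4.72 over 200 s) still matches `alpha = 4.42` within 0.5. In the
superdiffusive row (`m = 0.019`, `gamma = 0.95`) the network tail is
exponential-like with a Hill estimate of 5.1–5.6 at every step bin from 2
to 200 ms — far from the predicted 1.2 — robustly across noise floors.
Trajectory-level superdiffusion is unaffected (the measured `eta` is
0.71–0.82 in that row), so regime classification relies on `eta`, not on
the network tail.

## 4. Measuring the diffusion exponent

`diffusion_exponent()` implements the log–log regression of mean distance
on lag. The reduced position dynamics are second order: displacement
decorrelates over `tau_v / mu`, which is 78 ms in the diffusive row and 545
ms in the superdiffusive row. Below that crossover the motion is locally
ballistic and the fitted slope is biased towards 1. `classify_replay_regime()`
therefore fits at 100-ms lag bins up to 2 s and assumes runs of a minute or
more; with those defaults the three canonical parameter rows classify
correctly across seeds (measured bands: diffusive `eta` 0.54–0.61,
superdiffusive 0.71–0.82, stationary excursion below the interaction range
`a`).

## 5. Theta sweeps and the theta–replay experiment

With a moving location input, adaptation pushes the bump ahead of the
input, producing an oscillatory sweep. The bump holds a steady *positive*
lead (m-dependent, 0.013–0.065 m) and oscillates about it, so the decoded
offset typically never crosses zero. `theta_sweep_length()` therefore
segments cycles at ascending crossings of the *mean-centred* offset; for an
offset oscillating symmetrically about zero this coincides exactly with
zero-crossing segmentation (a pure `A * sin` oracle still yields `2A`), and
it remains well defined on a steady lead.

`run_theta_replay_correlation()` draws `m` uniformly from `[0.04, 0.08]` at
`gamma = 0.1` and correlates each network's mean sweep length with its
replay diffusion exponent. In this configuration the experiment is
**degenerate by construction**: every `m` in the range is 2–4 times the
motion threshold, so each replay run is a near-deterministic travelling
wave (9–13 m/s, no direction flips in 10 s) and `eta` is pinned at 1 with a
range of ~2e-4 across networks. Sweep length correlates almost perfectly
with `m` (r = 0.999), but correlating anything against a constant-up-to-noise
`eta` yields noise: the canonical run gives r = −0.53. A clearly positive
correlation would require an `m` range straddling the threshold, which
would change the experiment's definition; the package keeps the
configuration as specified and leaves the corresponding acceptance test
red.

## 6. Activity–step-size correlation

Replay steps are larger when the population activity is transiently lower
— structurally, the pooled correlation between the window-averaged
population rate and the step size is −0.43 across `m = 0.008`–`0.019`. The
observable quantity, however, is Poisson spike counts: the population
rate's coefficient of variation across windows is only 0.0018, so at the
default gain (≈42 counts per 20-ms window) Poisson noise dilutes the
correlation to an asymptote of about −0.005 (exact dilution formula
`rho * sd(lambda) / sqrt(var(lambda) + mean(lambda))`, verified by
replicates). Resolving the *sign* of a correlation that small needs ~1.6e5
windows; the acceptance configuration therefore pools 4 runs of 800 s.
Even at that size the canonical seed lands at r = +0.0002 (a different
seed under the identical configuration gives −0.0083, p < 0.001). The
acceptance test keeps the canonical seed and is left red; the sizing was
fixed from the dilution analysis before the run, and the residual
sign-flip risk is documented rather than tuned away.

## 7. Spectral generator analysis

`circulant_eigenvalues()` computes eigenvalues by DFT of the first row
(matching dense eigendecompositions to 1e-10), and a sub-diagonal
perturbation at offset `s` shifts every eigenvalue by a pure phase of
magnitude `eps`. For the lazy random walk on 100 states the principal mode
crosses from damped to amplified exactly at `s = 25` (partner 75) — the
exact, seed-free acceptance target. Small offsets uniformly suppress
low-frequency modes; offsets near `N/2` produce an oscillatory rescaling
pattern across modes. `evolve_states()` integrates the master equation with
clipping-and-renormalisation so the state stays a probability distribution,
and `sample_trajectory()` draws discrete state paths from it.

## 8. Estimator calibration fixtures

All estimators are calibrated on seeded synthetic fixtures
(`make_fixture()`): Brownian trajectories recover `eta = 0.5 ± 0.05`
(acceptance target), ballistic ones give exactly 1, Lévy walks exceed the
Brownian band, Pareto draws recover their tail exponent within 0.1, and
Gaussian tuning-curve rate maps on a linear track give a
population-vector-correlation index that decreases with field width. The
rate-map fixture is deliberately non-periodic: on a ring, wide fields
produce deep anticorrelation at the half-ring separation, which corrupts
the peak-to-trough slope that the index is built on, and the empirical
setting the index mimics is a linearised track.
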