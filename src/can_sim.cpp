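// Euler-Maruyama integration core of the CAN with firing-rate adaptation.
// Uses R's RNG so set.seed() controls every draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double wrap_pos(double x, double L) {
  return x - L * std::floor(x / L);
}

static inline double ring_dist(double x, double y, double L) {
  double d = wrap_pos(std::fabs(x - y), L);
  return std::min(d, L - d);
}

// mode: 0 = none, 1 = moving location bump, 2 = uniform sinusoidal drive
// [[Rcpp::export]]
List can_simulate_cpp(arma::vec U, arma::vec V, const arma::mat& J,
                      const arma::vec& xs,
                      double rho, double dx, double k,
                      double tau_u, double tau_v, double m,
                      double sigma_U, double sigma_m, double dt,
                      int n_steps, int record_every, bool record_state,
                      int mode, double beta, double v_ext_mps,
                      double a, double L,
                      double A_gamma, double omega_gamma, double phi_gamma,
                      double t0) {
  const int N = U.n_elem;
  const int n_rec = n_steps / record_every + 1;
  arma::vec times(n_rec), z(n_rec), act(n_rec);
  arma::mat U_t, V_t, r_t;
  if (record_state) {
    U_t.set_size(n_rec, N);
    V_t.set_size(n_rec, N);
    r_t.set_size(n_rec, N);
  }
  const double v_ext = v_ext_mps / 1000.0;  // m/s -> m/ms
  const arma::vec cosx = arma::cos(2.0 * M_PI * xs / L);
  const arma::vec sinx = arma::sin(2.0 * M_PI * xs / L);
  const double sqdt = std::sqrt(dt);

  arma::vec r(N), input(N, arma::fill::zeros), rec(N);
  int irec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double t = t0 + step * dt;
    // firing rate from current U (divisive global inhibition)
    arma::vec U2 = U % U;
    r = U2 / (1.0 + k * rho * dx * arma::accu(U2));

    if (step % record_every == 0) {
      times(irec) = t;
      double C = arma::dot(r, cosx), S = arma::dot(r, sinx);
      double ang = std::atan2(S, C);
      double zz = ang / (2.0 * M_PI) * L;
      z(irec) = wrap_pos(zz, L);
      act(irec) = arma::accu(r) * dx;
      if (record_state) {
        U_t.row(irec) = U.t();
        V_t.row(irec) = V.t();
        r_t.row(irec) = r.t();
      }
      ++irec;
    }
    if (step == n_steps) break;

    // external input
    if (mode == 1) {
      double zc = wrap_pos(v_ext * t, L);
      for (int i = 0; i < N; ++i) {
        double d = ring_dist(xs(i), zc, L);
        input(i) = beta * std::exp(-d * d / (2.0 * a * a));
      }
    } else if (mode == 2) {
      input.fill(A_gamma * std::sin(omega_gamma * t / 1000.0 + phi_gamma));
    }

    rec = rho * dx * (J * r);

    arma::vec etaU(N), etaV(N);
    if (sigma_U > 0) etaU = as<arma::vec>(rnorm(N)); else etaU.zeros();
    if (sigma_m > 0) etaV = as<arma::vec>(rnorm(N)); else etaV.zeros();

    arma::vec U_old = U;
    U += (dt / tau_u) * (-U_old + rec - V + input) +
         (sigma_U / tau_u) * sqdt * etaU;
    V += (dt / tau_v) * (-V + m * U_old) +
         (sigma_m / tau_v) * sqdt * (U_old % etaV);

    if (!U.is_finite() || !V.is_finite()) {
      stop("simulation became unstable at t = %f ms (dt = %f, N = %d); "
           "reduce dt or noise amplitudes", t, dt, N);
    }
  }

  List out = List::create(
    _["times"] = times, _["z"] = z, _["activity"] = act,
    _["U_final"] = U, _["V_final"] = V);
  if (record_state) {
    out["U_t"] = U_t;
    out["V_t"] = V_t;
    out["r_t"] = r_t;
  }
  return out;
}

// Langevin reduction of the bump-position dynamics:
//   tau_u dz = m s dt + a_z dW_z      (time rescaled by tau_u)
//   tau_v ds = -(mu + gamma xi) s dt + a_s dW_s   (time rescaled by tau_v)
// Euler-Maruyama, Ito convention; increments use sqrt(dt/tau).
// [[Rcpp::export]]
List langevin_simulate_cpp(double mu, double gamma, double a_z, double a_s,
                           double m, double tau_u, double tau_v,
                           double dt, int n_steps, int record_every,
                           double z0, double s0) {
  const int n_rec = n_steps / record_every + 1;
  arma::vec times(n_rec), zs(n_rec), ss(n_rec);
  double z = z0, s = s0;
  const double hu = dt / tau_u, hv = dt / tau_v;
  const double squ = std::sqrt(hu), sqv = std::sqrt(hv);
  int irec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % record_every == 0) {
      times(irec) = step * dt;
      zs(irec) = z;
      ss(irec) = s;
      ++irec;
    }
    if (step == n_steps) break;
    double n1 = norm_rand(), n2 = norm_rand(), n3 = norm_rand();
    double s_old = s;
    s += -mu * s_old * hv + sqv * (-gamma * s_old * n1 + a_s * n2);
    z += m * s_old * hu + squ * a_z * n3;
    if (!std::isfinite(s) || !std::isfinite(z)) {
      stop("Langevin integration became unstable at step %d (dt = %f)",
           step, dt);
    }
  }
  return List::create(_["times"] = times, _["z"] = zs, _["s"] = ss);
}
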