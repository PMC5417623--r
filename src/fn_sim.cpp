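#include <Rcpp.h>
#include <vector>
#include <deque>
#include "rng.h"

using namespace Rcpp;

static inline double fn_cubic(double v) { return v * (0.1 - v) * (v - 1.0); }

// numerically stable logistic form of the voltage-dependent recovery rate
static inline double fn_eps(double v, bool vdep, double eps_const,
                            double eps_lo, double eps_hi, double v_half,
                            double v_slope) {
  if (!vdep) return eps_const;
  const double x = (v - v_half) / v_slope;
  if (x > 0.0) {
    const double e = std::exp(-x);
    return (eps_hi * e + eps_lo) / (e + 1.0);
  }
  const double e = std::exp(x);
  return (eps_hi + eps_lo * e) / (1.0 + e);
}

// [[Rcpp::export]]
double epsilon_of_v_cpp(double v, double eps_lo, double eps_hi, double v_half,
                        double v_slope) {
  return fn_eps(v, true, 0.0, eps_lo, eps_hi, v_half, v_slope);
}

// Euler-Maruyama integration of the augmented FitzHugh-Nagumo ensemble.
//   tau_v dv = [v(0.1-v)(v-1) - w + A sin(2 pi phi t)] dt + sqrt(2 D) dW
//   dw      = eps(v) v dt
// Spikes are upward crossings of w through w_c (previous sample strictly
// below), linearly interpolated. Optionally records trajectories, the
// noise path xi_j = z_j / sqrt(dt), and an online spike-triggered average
// of xi over a (pre, post) window.
// [[Rcpp::export]]
List fn_simulate_cpp(List par, bool record_traj, bool record_noise,
                     bool do_sta, double sta_pre, double sta_post, double v0,
                     double w0) {
  const double tau_v = as<double>(par["tau_v"]);
  const bool vdep = as<bool>(par["vdep"]);
  const double eps_const = as<double>(par["eps_const"]);
  const double eps_lo = as<double>(par["eps_lo"]);
  const double eps_hi = as<double>(par["eps_hi"]);
  const double v_half = as<double>(par["v_half"]);
  const double v_slope = as<double>(par["v_slope"]);
  const double D = as<double>(par["D"]);
  const double A = as<double>(par["A"]);
  const double phi = as<double>(par["phi"]);
  const double w_c = as<double>(par["w_c"]);
  const double dt = as<double>(par["dt"]);
  const double duration = as<double>(par["duration"]);
  const int n_cells = as<int>(par["n_cells"]);
  const uint64_t seed = (uint64_t) as<double>(par["seed"]);

  const long long n_steps = (long long) std::llround(duration / dt);
  const double sq_noise = std::sqrt(2.0 * D * dt) / tau_v;
  const double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  const double two_pi_phi = 6.283185307179586 * phi;

  NumericMatrix traj_v, traj_w, noise_mat;
  if (record_traj) {
    traj_v = NumericMatrix(n_steps + 1, n_cells);
    traj_w = NumericMatrix(n_steps + 1, n_cells);
  }
  if (record_noise) noise_mat = NumericMatrix(n_steps, n_cells);

  const long long n_pre = do_sta ? (long long) std::llround(sta_pre / dt) : 0;
  const long long n_post = do_sta ? (long long) std::llround(sta_post / dt) : 0;
  const long long Lw = n_pre + n_post + 1;
  std::vector<double> sta_sum;
  long long sta_count = 0;
  if (do_sta) sta_sum.assign((size_t) Lw, 0.0);

  List spikes(n_cells);

  std::vector<double> ring;
  for (int c = 0; c < n_cells; ++c) {
    RngStream rng(seed, (uint64_t) c);
    double v = v0, w = w0;
    std::vector<double> sp;
    std::deque<long long> pending;
    if (do_sta) ring.assign((size_t) Lw, 0.0);
    if (record_traj) {
      traj_v(0, c) = v;
      traj_w(0, c) = w;
    }
    for (long long j = 0; j < n_steps; ++j) {
      const double t = j * dt;
      const double z = (D > 0.0) ? rng.normal() : 0.0;
      const double drive = (A > 0.0) ? A * std::sin(two_pi_phi * t) : 0.0;
      const double v_new =
          v + dt * (fn_cubic(v) - w + drive) / tau_v + sq_noise * z;
      const double w_new =
          w + dt * fn_eps(v, vdep, eps_const, eps_lo, eps_hi, v_half, v_slope) * v;
      if (!std::isfinite(v_new) || !std::isfinite(w_new) ||
          std::fabs(v_new) > 1e6) {
        stop("non-finite state at step %lld (t = %.4f ms), cell %d",
             j + 1, t + dt, c + 1);
      }
      if (w < w_c && w_new >= w_c) {
        sp.push_back(t + dt * (w_c - w) / (w_new - w));
        if (do_sta && j >= n_pre) pending.push_back(j);
      }
      if (record_noise) noise_mat(j, c) = z * inv_sqrt_dt;
      if (do_sta) {
        ring[(size_t)(j % Lw)] = z * inv_sqrt_dt;
        while (!pending.empty() && j == pending.front() + n_post) {
          const long long jp = pending.front();
          pending.pop_front();
          for (long long k = 0; k < Lw; ++k) {
            const long long idx = jp - n_pre + k;
            sta_sum[(size_t) k] += ring[(size_t)(idx % Lw)];
          }
          ++sta_count;
        }
      }
      v = v_new;
      w = w_new;
      if (record_traj) {
        traj_v(j + 1, c) = v;
        traj_w(j + 1, c) = w;
      }
    }
    spikes[c] = wrap(sp);
  }

  List out = List::create(_["spikes"] = spikes, _["n_steps"] = (double) n_steps);
  if (record_traj) {
    out["v"] = traj_v;
    out["w"] = traj_w;
  }
  if (record_noise) out["noise"] = noise_mat;
  if (do_sta) {
    out["sta_sum"] = wrap(sta_sum);
    out["sta_count"] = (double) sta_count;
  }
  return out;
}

// Fixed-step classical Runge-Kutta (RK4) for the deterministic system,
// optionally with the sinusoidal drive.
// [[Rcpp::export]]
List fn_rk4_cpp(List par, double v0, double w0, double t_end, double dt) {
  const double tau_v = as<double>(par["tau_v"]);
  const bool vdep = as<bool>(par["vdep"]);
  const double eps_const = as<double>(par["eps_const"]);
  const double eps_lo = as<double>(par["eps_lo"]);
  const double eps_hi = as<double>(par["eps_hi"]);
  const double v_half = as<double>(par["v_half"]);
  const double v_slope = as<double>(par["v_slope"]);
  const double A = as<double>(par["A"]);
  const double phi = as<double>(par["phi"]);
  const double two_pi_phi = 6.283185307179586 * phi;

  const long long n = (long long) std::llround(t_end / dt);
  NumericVector tv(n + 1), vv(n + 1), wv(n + 1);
  double v = v0, w = w0;
  vv[0] = v;
  wv[0] = w;
  tv[0] = 0.0;

#define FN_DV(vx, wx, tx) \
  ((fn_cubic(vx) - (wx) + ((A > 0.0) ? A * std::sin(two_pi_phi * (tx)) : 0.0)) / tau_v)
#define FN_DW(vx) \
  (fn_eps(vx, vdep, eps_const, eps_lo, eps_hi, v_half, v_slope) * (vx))

  for (long long j = 0; j < n; ++j) {
    const double t = j * dt;
    const double k1v = FN_DV(v, w, t);
    const double k1w = FN_DW(v);
    const double k2v = FN_DV(v + 0.5 * dt * k1v, w + 0.5 * dt * k1w, t + 0.5 * dt);
    const double k2w = FN_DW(v + 0.5 * dt * k1v);
    const double k3v = FN_DV(v + 0.5 * dt * k2v, w + 0.5 * dt * k2w, t + 0.5 * dt);
    const double k3w = FN_DW(v + 0.5 * dt * k2v);
    const double k4v = FN_DV(v + dt * k3v, w + dt * k3w, t + dt);
    const double k4w = FN_DW(v + dt * k3v);
    v += dt * (k1v + 2.0 * k2v + 2.0 * k3v + k4v) / 6.0;
    w += dt * (k1w + 2.0 * k2w + 2.0 * k3w + k4w) / 6.0;
    if (!std::isfinite(v) || !std::isfinite(w) || std::fabs(v) > 1e6) {
      stop("non-finite state at step %lld (t = %.4f ms)", j + 1, t + dt);
    }
    tv[j + 1] = (j + 1) * dt;
    vv[j + 1] = v;
    wv[j + 1] = w;
  }
#undef FN_DV
#undef FN_DW

  return List::create(_["t"] = tv, _["v"] = vv, _["w"] = wv);
}
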