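#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// positive wrap onto [0, T); avoids std::fmod (whose symbol version is
// newer than some host C libraries provide)
static inline double wrapT(double x, double T) {
  return x - std::floor(x / T) * T;
}

// Thinning (rejection) simulation of the two-barrier escape process.
// Candidate events arrive as a homogeneous Poisson process with rate
// 2*gamma (each hazard is bounded by gamma); candidates are accepted as
// left crossings or spikes with probabilities H_L/2gamma and H_R/2gamma
// evaluated at the current state. Both event types reset the moving-barrier
// clock. Variants: 0 = phasic (left barrier active, moving right barrier),
// 1 = right_moving (no left barrier, moving right barrier),
// 2 = classic (no left barrier, constant right barrier v_R).
// Sinusoid clock: 0 = absolute time, 1 = per_reset (exogenous: phase offset
// updated at each spike to (ISI + psi0) mod T, mirroring the renewal
// theory's bookkeeping), 2 = endogenous (fixed offset psi0 after every
// reset).
// [[Rcpp::export]]
List barrier_mc_cpp(List spec, double t_end, double seed, int clock,
                    double psi0_init) {
  const int variant = as<int>(spec["variant_code"]);
  const double gamma = as<double>(spec["gamma"]);
  const double beta = as<double>(spec["beta"]);
  const double p_exp = as<double>(spec["p_exp"]);
  const double dU_L = as<double>(spec["dU_L"]);
  const double v_R = as<double>(spec["v_R"]);
  const double mb_amp = as<double>(spec["mb_amp"]);
  const double mb_freq = as<double>(spec["mb_freq"]);
  const double mb_shift1 = as<double>(spec["mb_shift1"]);
  const double mb_decay = as<double>(spec["mb_decay"]);
  const double mb_shift2 = as<double>(spec["mb_shift2"]);
  const double D = as<double>(spec["D"]);
  const double A = as<double>(spec["A"]);
  const double phi = as<double>(spec["phi"]);

  const bool has_left = (variant == 0);
  const bool moving = (variant != 2);
  const double two_pi_phi = 6.283185307179586 * phi;
  const double T = (phi > 0.0) ? 1.0 / phi : 0.0;
  const double bound = 2.0 * gamma;

  RngStream rng((uint64_t) seed, 0);

  std::vector<double> spikes, lefts, phases;
  double t = 0.0;       // absolute time
  double s = 0.0;       // time since last reset (either event type)
  double t_sp = 0.0;    // time since last spike
  double psi0 = psi0_init;

  while (true) {
    double u = rng.unif();
    while (u <= 0.0) u = rng.unif();
    const double gap = -std::log(u) / bound;
    t += gap;
    s += gap;
    t_sp += gap;
    if (t > t_end) break;

    double sig = 0.0;
    if (A > 0.0) {
      const double arg = (clock == 0) ? t : (s + psi0);
      sig = A * std::sin(two_pi_phi * arg);
    }
    double dUR = v_R;
    if (moving) {
      dUR -= mb_amp * std::sin(mb_freq * (s + mb_shift1)) *
             std::exp(-mb_decay * (s + mb_shift2));
    }
    const double bR = dUR - sig;
    if (bR < 0.0)
      stop("right barrier collapsed (height %.4f at t = %.4f); A too large",
           bR, t);
    const double hR = gamma * std::exp(-beta * std::pow(bR, p_exp) / D);
    double hL = 0.0;
    if (has_left) {
      const double bL = dU_L - sig;
      if (bL < 0.0)
        stop("left barrier collapsed (height %.4f at t = %.4f); A too large",
             bL, t);
      hL = gamma * std::exp(-beta * std::pow(bL, p_exp) / D);
    }

    const double a = rng.unif();
    if (a < hL / bound) {
      lefts.push_back(t);
      s = 0.0;  // left crossing resets the moving-barrier (and kernel) clock
    } else if (a < (hL + hR) / bound) {
      spikes.push_back(t);
      if (phi > 0.0) {
        double psi;
        if (clock == 0) {
          psi = wrapT(t, T);
        } else if (clock == 1) {
          psi = wrapT(t_sp + psi0, T);
          psi0 = psi;
        } else {
          psi = wrapT(t_sp + psi0, T);
        }
        phases.push_back(psi);
      }
      s = 0.0;
      t_sp = 0.0;
    }
  }

  return List::create(_["spike_times"] = wrap(spikes),
                      _["left_times"] = wrap(lefts),
                      _["spike_phases"] = wrap(phases),
                      _["t_end"] = t_end);
}
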