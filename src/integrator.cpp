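// Fixed-substep integrator for the synthetic immature-cardiomyocyte membrane
// model with an optional zero-order-hold IK1 injection loop (the virtual
// dynamic clamp). Gates use exact exponential (Rush-Larsen) updates; the
// membrane potential uses forward Euler at dt_sample/n_sub. The injected
// current is recomputed once per sample from the voltage at the start of the
// interval and held constant within it, emulating a 5 kHz real-time loop with
// one-sample latency.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gate_step(double x, double xinf, double decay) {
  return xinf + (x - xinf) * decay;
}
static inline double xk1_inf_c(double V, double Ko, double mid) {
  return 1.0 / (1.0 + std::exp(-(V + 2.5538 * Ko + mid) /
                               (1.5692 * Ko + 3.8115)));
}
static inline double xk1_tau_c(double V) {
  return 122.2 / (std::exp(-(V + 127.2) / 20.36) +
                  std::exp((V + 236.8) / 69.33));
}
static inline double rk1_c(double V, double Ko, double mid, double slope) {
  return 1.0 / (1.0 + std::exp((V + mid - 2.6 * Ko) / slope));
}
// Koivumaki/Nygren-shaped current, V in mV (exponent scaled by 1/1000).
static inline double ik1_atr_c(double V, double G, double Ko, double EK,
                               double frt1000) {
  return G * std::pow(Ko, 0.4457) * (V - EK) /
         (1.0 + std::exp(1.5 * (V - EK + 3.6) * frt1000));
}

// Injection segment columns: 0 start_sample, 1 type (0 none, 1 gated
// ventricular-family, 2 atrial), 2 G_eff, 3 xinf_mid, 4 rk1_mid, 5 rk1_slope.
// [[Rcpp::export]]
List sim_cell_cpp(NumericVector cellp, double Ko, double EK, double T,
                  double dt_sample, int n_samples, int n_sub,
                  NumericVector stim_onsets, double stim_dur, double stim_amp,
                  NumericMatrix segs, NumericVector noise, double V0,
                  bool continuous_inj, Nullable<Function> injected_fn) {
  const double gNa = cellp["g_Na"], gCaL = cellp["g_CaL"],
               gKrep = cellp["g_Krep"], gKur = cellp["g_Kur"],
               gK1n = cellp["g_K1_native"], gleak = cellp["g_leak"],
               Eleak = cellp["E_leak"], tau_f = cellp["tau_f"],
               tau_n = cellp["tau_n"];
  const double ENa = 50.0, ECa = 60.0;
  const double frt1000 = 96485.0 / (8.314 * T * 1000.0);
  const double dt = dt_sample / n_sub;
  // constant-tau gate decay factors, precomputed once
  const double em = std::exp(-dt / 0.25), eh = std::exp(-dt / 3.0),
               ed = std::exp(-dt / 2.0), ef = std::exp(-dt / tau_f),
               en = std::exp(-dt / tau_n), ea = std::exp(-dt / 2.0),
               ei = std::exp(-dt / 300.0);

  double V = V0;
  double m = 1.0 / (1.0 + std::exp(-(V + 40.0) / 6.0));
  double h = 1.0 / (1.0 + std::exp((V + 65.0) / 5.0));
  double d = 1.0 / (1.0 + std::exp(-(V + 10.0) / 6.0));
  double f = 1.0 / (1.0 + std::exp((V + 25.0) / 5.0));
  double n = 1.0 / (1.0 + std::exp(-(V + 15.0) / 8.0));
  double a = 1.0 / (1.0 + std::exp(-(V + 5.0) / 8.0));
  double iu = 1.0 / (1.0 + std::exp((V + 30.0) / 10.0));

  NumericVector Vout(n_samples), Iout(n_samples);
  bool ok = true;
  int err_sample = -1;

  int seg_i = -1, next_seg = 0;
  const int nseg = segs.nrow();
  int seg_type = 0;
  double seg_G = 0, seg_xmid = 144.59, seg_rmid = 105.8, seg_rslope = 9.493;
  double xk1 = 0.0;
  Function fn = injected_fn.isNotNull() ? Function(injected_fn.get())
                                        : Function("identity");
  const bool has_fn = injected_fn.isNotNull();
  const bool has_noise = noise.size() > 0;
  int stim_i = 0;
  const int n_stim = stim_onsets.size();

  for (int i = 0; i < n_samples; ++i) {
    const double t = i * dt_sample;
    // activate any scheduled injection segment at this sampling instant
    while (next_seg < nseg && i >= (int)segs(next_seg, 0)) {
      seg_i = next_seg;
      seg_type = (int)segs(seg_i, 1);
      seg_G = segs(seg_i, 2);
      seg_xmid = segs(seg_i, 3);
      seg_rmid = segs(seg_i, 4);
      seg_rslope = segs(seg_i, 5);
      if (seg_type == 1) xk1 = xk1_inf_c(V, Ko, seg_xmid);  // gate re-init
      ++next_seg;
    }
    // injected current from the most recent sample (zero-order hold)
    double Iinj = 0.0;
    if (seg_type == 1)
      Iinj = seg_G * std::sqrt(Ko) * xk1 * rk1_c(V, Ko, seg_rmid, seg_rslope) *
             (V - EK);
    else if (seg_type == 2)
      Iinj = ik1_atr_c(V, seg_G, Ko, EK, frt1000);
    if (has_fn) Iinj += as<double>(fn(V, t));
    if (has_noise) Iinj += noise[i];

    Vout[i] = V;
    Iout[i] = Iinj;
    if (i == n_samples - 1) break;

    if (seg_type == 1 && !continuous_inj) {
      // carry the injected gate across samples (Rush-Larsen over dt_sample)
      const double xi = xk1_inf_c(V, Ko, seg_xmid);
      xk1 = xi + (xk1 - xi) * std::exp(-dt_sample / xk1_tau_c(V));
    }

    for (int s = 0; s < n_sub; ++s) {
      const double ts = t + s * dt;
      while (stim_i < n_stim && ts >= stim_onsets[stim_i] + stim_dur) ++stim_i;
      const double Ist =
          (stim_i < n_stim && ts >= stim_onsets[stim_i]) ? stim_amp : 0.0;

      if (continuous_inj) {  // continuously-coupled reference mode
        if (seg_type == 1) {
          const double xi = xk1_inf_c(V, Ko, seg_xmid);
          xk1 = xi + (xk1 - xi) * std::exp(-dt / xk1_tau_c(V));
          Iinj = seg_G * std::sqrt(Ko) * xk1 *
                 rk1_c(V, Ko, seg_rmid, seg_rslope) * (V - EK);
        } else if (seg_type == 2) {
          Iinj = ik1_atr_c(V, seg_G, Ko, EK, frt1000);
        }
        if (has_noise) Iinj = Iinj + noise[i];
      }

      // cell gates (constant taus, exact exponential updates)
      m = gate_step(m, 1.0 / (1.0 + std::exp(-(V + 40.0) / 6.0)), em);
      h = gate_step(h, 1.0 / (1.0 + std::exp((V + 65.0) / 5.0)), eh);
      d = gate_step(d, 1.0 / (1.0 + std::exp(-(V + 10.0) / 6.0)), ed);
      // small non-inactivating pedestal sustains the plateau
      f = gate_step(f, 0.05 + 0.95 / (1.0 + std::exp((V + 25.0) / 5.0)), ef);
      n = gate_step(n, 1.0 / (1.0 + std::exp(-(V + 15.0) / 8.0)), en);
      a = gate_step(a, 1.0 / (1.0 + std::exp(-(V + 5.0) / 8.0)), ea);
      iu = gate_step(iu, 1.0 / (1.0 + std::exp((V + 30.0) / 10.0)), ei);

      const double INa = gNa * m * m * m * h * (V - ENa);
      const double ICaL = gCaL * d * f * (V - ECa);
      const double IKrep = gKrep * n * (V - EK);
      const double IKur = gKur * a * iu * (V - EK);
      // weak, mildly rectified immature background K+ current
      const double IK1n =
          gK1n * (V - EK) / (1.0 + std::exp((V + 40.0) / 30.0));
      const double Ileak = gleak * (V - Eleak);

      V += dt * (-(INa + ICaL + IKrep + IKur + IK1n + Ileak + Iinj) + Ist);
    }
    if (!std::isfinite(V) || std::fabs(V) > 150.0) {
      ok = false;
      err_sample = i + 1;
      break;
    }
  }

  return List::create(_["V"] = Vout, _["I"] = Iout, _["ok"] = ok,
                      _["err_sample"] = err_sample, _["xk1_end"] = xk1);
}
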