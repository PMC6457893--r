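#include <Rcpp.h>
using namespace Rcpp;

// Integrate-and-fire simulation with current-based dual-exponential synapses.
//
// The subthreshold dynamics are linear,
//   tau_m dV/dt = E_l - V + sum_k (a_fast_k(t) + a_slow_k(t)),
// where each synaptic state a(t) decays exponentially and jumps by
// scale * w / tau at an input spike.  Because the system is linear with
// piecewise-exponential input, each 0.05 ms step is advanced with the exact
// closed-form solution (no Euler error): for a synaptic component with
// amplitude a and time constant tau_s, the particular solution contributes
// C = a * tau_s / (tau_s - tau_m), and
//   u(t+dt) = (u(t) - sum C) * exp(-dt/tau_m) + sum C * exp(-dt/tau_s)
// with u = V - E_l.  Threshold crossings are detected on the grid; after a
// spike V is held at v_reset for the refractory period.  Synaptic states
// keep evolving during the refractory period.
//
// spike_idx must be sorted ascending; spike_site is 0-based.

// [[Rcpp::export]]
List cpp_simulate_if(double dt, int n_steps, double tau_m, double E_l,
                     double theta, double v_reset, double t_ref,
                     IntegerVector spike_idx, IntegerVector spike_site,
                     NumericVector spike_scale,
                     NumericVector tau_fast, NumericVector w_fast,
                     NumericVector tau_slow, NumericVector w_slow,
                     bool subthreshold) {
  const int n_sites = tau_fast.size();
  std::vector<double> af(n_sites, 0.0), as(n_sites, 0.0);
  std::vector<double> df(n_sites), ds(n_sites), cf(n_sites), cs(n_sites);
  const double em = std::exp(-dt / tau_m);
  for (int k = 0; k < n_sites; k++) {
    double tf = tau_fast[k], ts = tau_slow[k];
    // guard exact degeneracy with the membrane time constant
    if (std::fabs(tf - tau_m) < 1e-9) tf += 1e-6;
    if (std::fabs(ts - tau_m) < 1e-9) ts += 1e-6;
    df[k] = std::exp(-dt / tf);
    ds[k] = std::exp(-dt / ts);
    cf[k] = tf / (tf - tau_m);
    cs[k] = ts / (ts - tau_m);
  }

  NumericVector V(n_steps);
  std::vector<double> out_spikes;
  double u = 0.0;  // V - E_l
  int sp = 0;
  const int m = spike_idx.size();
  double refr_until = -1e30;

  for (int i = 0; i < n_steps; i++) {
    const double t = i * dt;
    while (sp < m && spike_idx[sp] == i) {
      const int k = spike_site[sp];
      af[k] += spike_scale[sp] * w_fast[k] / tau_fast[k];
      as[k] += spike_scale[sp] * w_slow[k] / tau_slow[k];
      sp++;
    }
    if (!subthreshold && t < refr_until) {
      u = v_reset - E_l;
      V[i] = v_reset;
    } else {
      V[i] = E_l + u;
      if (!subthreshold && V[i] >= theta) {
        out_spikes.push_back(t);
        refr_until = t + t_ref;
        u = v_reset - E_l;
        V[i] = theta;  // mark the crossing sample at threshold
      }
    }
    // exact advance over [t, t + dt]
    double csum_now = 0.0, csum_next = 0.0;
    for (int k = 0; k < n_sites; k++) {
      const double C = cf[k] * af[k] + cs[k] * as[k];
      csum_now += C;
      af[k] *= df[k];
      as[k] *= ds[k];
      csum_next += cf[k] * af[k] + cs[k] * as[k];
    }
    u = (u - csum_now) * em + csum_next;
    if (!subthreshold && (i + 1) * dt < refr_until) u = v_reset - E_l;
  }
  return List::create(_["voltage"] = V,
                      _["spike_times"] = NumericVector(out_spikes.begin(),
                                                       out_spikes.end()));
}
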