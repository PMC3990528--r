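// Conductance-synapse leaky integrate-and-fire network core.
//
// State per neuron: membrane potential V (mV, relative to rest) and six
// synaptic state variables -- a decaying and a rising exponential for each
// of the three current types (external, recurrent excitatory, recurrent
// inhibitory). The difference-of-exponentials conductance of type k is
//   g_k = (D_k - R_k) / norm_k,
// where norm_k peak-normalises the kernel so efficacies are peak
// conductances relative to leak. D and R decay exactly between events
// (D *= exp(-dt/tau_d), R *= exp(-dt/tau_r)) and both jump by the efficacy
// J when a spike arrives, so the synaptic linear subsystem is integrated
// exactly. The membrane uses exponential Euler per step:
//   V <- Vinf + (V - Vinf) * exp(-dt (1 + g_tot) / tau_m),
//   Vinf = (g_ext + g_exc) Ve / (1 + g_tot)   (inhibitory reversal = rest).
//
// Spikes are detected at step boundaries (V >= threshold at end of step),
// V is reset and clamped for the class refractory period while synaptic
// conductances keep integrating, and emitted spikes are delivered to all
// out-neighbours after the onset latency via a circular pending buffer.
// External Poisson spike trains are generated per neuron from exponential
// inter-arrival times using one splitmix64 counter stream per neuron, so
// identical seeds give identical arrival times independently of dt.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// exp(-x) for x >= 0; polynomial branch keeps the hot loop out of libm.
static inline double expneg(double x) {
  if (x > 0.5) return std::exp(-x);
  // degree-7 Taylor (Horner), |err| <= x^8/8! < 1.1e-7 at x = 0.5
  return 1.0 - x * (1.0 - x * 0.5 * (1.0 - x / 3.0 * (1.0 - x * 0.25 *
         (1.0 - x * 0.2 * (1.0 - x / 6.0 * (1.0 - x / 7.0))))));
}

// splitmix64: one independent, dt-invariant stream per neuron for the
// external Poisson arrivals (arrival times then do not depend on the
// integration step, only on the seed and the neuron id).
static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01_sm(uint64_t &s) {
  return (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n, int n_exc,
              IntegerVector out_ptr, IntegerVector out_idx,
              List neuron, List synapse, NumericVector kscale,
              double dt, int n_steps, int latency_steps,
              double ext_rate, int seed, int sample_every,
              bool rec_lfp, bool rec_v, bool rec_cur, bool rec_g,
              IntegerVector rec_nodes, NumericVector v_init) {
  const double tau_m[2] = { as<double>(neuron["tau_m_exc"]),
                            as<double>(neuron["tau_m_inh"]) };
  const double vrev_e = as<double>(neuron["v_rev_exc"]);
  const double vrev_i = as<double>(neuron["v_rev_inh"]);
  const double vth = as<double>(neuron["v_thresh"]);
  const double vreset = as<double>(neuron["v_reset"]);
  const int refrac_steps[2] = {
    (int)std::lround(as<double>(neuron["refrac_exc"]) / dt),
    (int)std::lround(as<double>(neuron["refrac_inh"]) / dt) };

  // kernel time constants per (source sign, target type); ext shares exc
  NumericVector rise = synapse["rise"], decay = synapse["decay"],
                eff = synapse["efficacy"];
  // order in R: ee, ie, ei, ii  (source-target)
  const double tr_exc[2] = { rise[0], rise[2] };
  const double td_exc[2] = { decay[0], decay[2] };
  const double tr_inh[2] = { rise[1], rise[3] };
  const double td_inh[2] = { decay[1], decay[3] };
  // efficacy order in R: ee, ie, ei, ii, ext_e, ext_i
  const double j_exc[2] = { eff[0], eff[2] };   // E source -> (E, I) target
  const double j_inh[2] = { eff[1], eff[3] };   // I source -> (E, I) target
  const double j_ext[2] = { eff[4], eff[5] };

  // kernel prefactors per (source sign, target type), computed in R from
  // the kernel_norm convention: kscale = (exc->E, exc->I, inh->E, inh->I)
  const double invn_exc[2] = { kscale[0], kscale[1] };
  const double invn_inh[2] = { kscale[2], kscale[3] };
  double fD_exc[2], fR_exc[2], fD_inh[2], fR_inh[2];
  for (int c = 0; c < 2; ++c) {
    fD_exc[c] = std::exp(-dt / td_exc[c]);
    fR_exc[c] = std::exp(-dt / tr_exc[c]);
    fD_inh[c] = std::exp(-dt / td_inh[c]);
    fR_inh[c] = std::exp(-dt / tr_inh[c]);
  }

  std::vector<double> V(n, 0.0);
  if (v_init.size() == n)
    for (int i = 0; i < n; ++i) V[i] = v_init[i];
  std::vector<double>
      Dxt(n, 0.0), Rxt(n, 0.0), Dxc(n, 0.0), Rxc(n, 0.0),
      Din(n, 0.0), Rin(n, 0.0),
      g_ext(n, 0.0), g_exc(n, 0.0), g_inh(n, 0.0);
  std::vector<int> refrac(n, 0);
  std::vector<unsigned char> isE(n);
  for (int i = 0; i < n; ++i) isE[i] = (i < n_exc);

  const int L = latency_steps + 1;
  std::vector<double> pend_ext((size_t)L * n, 0.0),
                      pend_exc((size_t)L * n, 0.0),
                      pend_inh((size_t)L * n, 0.0);

  std::vector<uint64_t> ext_state(n);
  std::vector<double> next_ext(n);
  const double inv_rate = ext_rate > 0 ? 1.0 / ext_rate : 0.0;
  for (int i = 0; i < n; ++i) {
    uint64_t h = (uint64_t)seed;
    ext_state[i] = splitmix64(h) ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(i + 1));
    next_ext[i] = ext_rate > 0
      ? -std::log(1.0 - unif01_sm(ext_state[i])) * inv_rate
      : std::numeric_limits<double>::infinity();
  }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> spiked; spiked.reserve(256);

  const int n_samples = n_steps / sample_every;
  NumericVector lfp(rec_lfp ? n_samples : 0);
  const int n_rec = rec_nodes.size();
  NumericMatrix v_m((rec_v ? n_samples : 0), (rec_v ? n_rec : 0));
  NumericMatrix iext_m((rec_cur ? n_samples : 0), (rec_cur ? n_rec : 0)),
                iexc_m((rec_cur ? n_samples : 0), (rec_cur ? n_rec : 0)),
                iinh_m((rec_cur ? n_samples : 0), (rec_cur ? n_rec : 0));
  NumericMatrix gext_m((rec_g ? n_samples : 0), (rec_g ? n_rec : 0)),
                gexc_m((rec_g ? n_samples : 0), (rec_g ? n_rec : 0)),
                ginh_m((rec_g ? n_samples : 0), (rec_g ? n_rec : 0));

  for (int s = 0; s < n_steps; ++s) {
    const int slot = s % L;
    const int dslot = (s + latency_steps) % L;
    const double t_end = (s + 1) * dt;
    double *px = &pend_ext[(size_t)slot * n];
    double *pc = &pend_exc[(size_t)slot * n];
    double *pi = &pend_inh[(size_t)slot * n];
    double *dx = &pend_ext[(size_t)dslot * n];

    // schedule external arrivals that fall inside this step
    if (ext_rate > 0) {
      for (int i = 0; i < n; ++i) {
        while (next_ext[i] < t_end) {
          dx[i] += j_ext[isE[i] ? 0 : 1];
          next_ext[i] += -std::log(1.0 - unif01_sm(ext_state[i])) * inv_rate;
        }
      }
    }

    spiked.clear();
    for (int i = 0; i < n; ++i) {
      const int c = isE[i] ? 0 : 1;
      // deliver pending, then exact exponential decay of synaptic states
      double dxt = (Dxt[i] + px[i]) * fD_exc[c];
      double rxt = (Rxt[i] + px[i]) * fR_exc[c];
      double dxc = (Dxc[i] + pc[i]) * fD_exc[c];
      double rxc = (Rxc[i] + pc[i]) * fR_exc[c];
      double din = (Din[i] + pi[i]) * fD_inh[c];
      double rin = (Rin[i] + pi[i]) * fR_inh[c];
      px[i] = pc[i] = pi[i] = 0.0;
      // flush decayed-out states to zero to avoid subnormal stalls
      const double TINY = 1e-120;
      if (dxt < TINY) dxt = 0.0; if (rxt < TINY) rxt = 0.0;
      if (dxc < TINY) dxc = 0.0; if (rxc < TINY) rxc = 0.0;
      if (din < TINY) din = 0.0; if (rin < TINY) rin = 0.0;
      Dxt[i] = dxt; Rxt[i] = rxt; Dxc[i] = dxc; Rxc[i] = rxc;
      Din[i] = din; Rin[i] = rin;
      const double gx = (dxt - rxt) * invn_exc[c];
      const double gc = (dxc - rxc) * invn_exc[c];
      const double gi = (din - rin) * invn_inh[c];
      g_ext[i] = gx; g_exc[i] = gc; g_inh[i] = gi;

      if (refrac[i] > 0) {
        V[i] = vreset;
        --refrac[i];
        continue;
      }
      const double gtot = gx + gc + gi;
      const double denom = 1.0 + gtot;
      const double vinf = ((gx + gc) * vrev_e + gi * vrev_i) / denom;
      const double v1 = vinf + (V[i] - vinf) * expneg(dt * denom / tau_m[c]);
      if (v1 >= vth) {
        V[i] = vreset;
        refrac[i] = refrac_steps[c];
        spike_t.push_back(t_end);
        spike_id.push_back(i + 1);
        spiked.push_back(i);
      } else {
        V[i] = v1;
      }
    }

    if (!std::isfinite(V[0]) || (n > 1 && !std::isfinite(V[n - 1])))
      stop("non-finite membrane potential at t = %f ms", t_end);

    // deliver emitted spikes to out-neighbours after the onset latency
    if (!spiked.empty()) {
      double *qx = &pend_exc[(size_t)dslot * n];
      double *qi = &pend_inh[(size_t)dslot * n];
      for (int o : spiked) {
        if (isE[o]) {
          for (int e = out_ptr[o]; e < out_ptr[o + 1]; ++e) {
            const int t = out_idx[e];
            qx[t] += j_exc[isE[t] ? 0 : 1];
          }
        } else {
          for (int e = out_ptr[o]; e < out_ptr[o + 1]; ++e) {
            const int t = out_idx[e];
            qi[t] += j_inh[isE[t] ? 0 : 1];
          }
        }
      }
    }

    if ((s + 1) % sample_every == 0) {
      const int k = (s + 1) / sample_every - 1;
      if (rec_lfp) {
        double acc = 0.0;
        for (int i = 0; i < n_exc; ++i) {
          acc += std::fabs(g_ext[i] * (vrev_e - V[i]))
               + std::fabs(g_exc[i] * (vrev_e - V[i]))
               + std::fabs(g_inh[i] * (vrev_i - V[i]));
        }
        lfp[k] = acc;
      }
      if (rec_v || rec_cur || rec_g) {
        for (int r = 0; r < n_rec; ++r) {
          const int i = rec_nodes[r];
          if (rec_v) v_m(k, r) = V[i];
          if (rec_cur) {
            iext_m(k, r) = g_ext[i] * (vrev_e - V[i]);
            iexc_m(k, r) = g_exc[i] * (vrev_e - V[i]);
            iinh_m(k, r) = g_inh[i] * (vrev_i - V[i]);
          }
          if (rec_g) {
            gext_m(k, r) = g_ext[i];
            gexc_m(k, r) = g_exc[i];
            ginh_m(k, r) = g_inh[i];
          }
        }
      }
    }
    if (s % 20000 == 0) checkUserInterrupt();
  }

  return List::create(
    _["spike_times"] = wrap(spike_t),
    _["spike_ids"] = wrap(spike_id),
    _["lfp"] = lfp,
    _["v"] = v_m,
    _["i_ext"] = iext_m, _["i_exc"] = iexc_m, _["i_inh"] = iinh_m,
    _["g_ext"] = gext_m, _["g_exc"] = gexc_m, _["g_inh"] = ginh_m,
    _["n_samples"] = n_samples);
}
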