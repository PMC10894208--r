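// Two-compartment conductance-based microcircuit integrator.
//
// Each neuron has a soma and a dendrite coupled by an axial conductance.
// Pyramidal cells carry I_Na, I_Kv, I_Km, I_Ca, I_KCa and leak at the soma
// and a passive dendrite (synaptic input + field coupling); fast-spiking
// interneurons carry I_Na, I_Kv and leak only.
// Kinetics follow the standard Traub/Pospischil-style rate functions with a
// threshold-shift parameter VT; the calcium-dependent potassium current uses
// a first-order calcium pool with an instantaneous activation
// Ca/(Ca + KD). Synapses are peak-normalised dual exponentials
// (rise tau1, decay tau2); NMDA carries the sigmoidal Mg-block factor.
// A spatially uniform sinusoidal field couples through the extracellular
// potential difference along each soma-dendrite axis.
//
// Units: mV, ms, nF, uS, nA, mM. Gating via exponential Euler; the two
// membrane voltages are updated with an implicit (backward-Euler) 2x2 solve
// per neuron per step, conductances frozen at the current gating state.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <random>
using namespace Rcpp;

// parameter vector layout per neuron (see build_default_circuit in R/)
enum NeuronPar {
  P_CS = 0, P_CD, P_GC,
  P_GNA_S, P_GKV_S, P_GKM_S, P_GL_S,
  P_GCA_S, P_GKCA_S, P_GL_D,
  P_EL, P_VT, P_POLUM, P_IINJ,
  NPAR
};

static inline double vtrap(double x, double y) {
  // x / (exp(x / y) - 1) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct Gates {
  double m, h, n, p, q, r, ca;
};

struct RateOut { double inf, tau; };

static inline void na_rates(double v, double vt, double &am, double &bm,
                            double &ah, double &bh) {
  am = 0.32 * vtrap(-(v - vt - 13.0), 4.0);
  bm = 0.28 * vtrap(v - vt - 40.0, 5.0);
  ah = 0.128 * std::exp(-(v - vt - 17.0) / 18.0);
  bh = 4.0 / (1.0 + std::exp(-(v - vt - 40.0) / 5.0));
}

static inline void kv_rates(double v, double vt, double &an, double &bn) {
  an = 0.032 * vtrap(-(v - vt - 15.0), 5.0);
  bn = 0.5 * std::exp(-(v - vt - 10.0) / 40.0);
}

static inline RateOut km_rate(double v) {
  RateOut o;
  o.inf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  o.tau = 1000.0 / (3.3 * std::exp((v + 35.0) / 20.0) +
                    std::exp(-(v + 35.0) / 20.0));
  return o;
}

static inline void ca_rates(double v, double &aq, double &bq, double &ar,
                            double &br) {
  aq = 0.055 * vtrap(-27.0 - v, 3.8);
  bq = 0.94 * std::exp((-75.0 - v) / 17.0);
  ar = 0.000457 * std::exp((-13.0 - v) / 50.0);
  br = 0.0065 / (std::exp((-15.0 - v) / 28.0) + 1.0);
}

static inline double expEuler(double x, double inf, double tau, double dt) {
  return inf + (x - inf) * std::exp(-dt / tau);
}

static inline double mg_block(double v) {
  // [Mg2+] = 1 mM sigmoidal block
  return 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
}

struct Synapse {
  int post, post_comp;       // comp: 0 soma, 1 dendrite
  int is_nmda;
  double E, w;
  double dec1, dec2;         // per-step decay factors exp(-dt/tau)
  double invpeak;
  double R, D;               // rise / decay states
  double g(double vpost) const {
    double gg = w * invpeak * (D - R);
    if (gg < 0) gg = 0;
    if (is_nmda) gg *= mg_block(vpost);
    return gg;
  }
};

static double dualexp_invpeak(double tau1, double tau2) {
  double tp = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
  double peak = std::exp(-tp / tau2) - std::exp(-tp / tau1);
  return 1.0 / peak;
}

// [[Rcpp::export]]
List simulate_circuit_cpp(NumericMatrix neuron_pars,  // NPAR x n_neurons
                          DataFrame synapses,
                          NumericVector poisson_rate, // Hz per neuron
                          NumericVector poisson_w,    // uS per neuron
                          double poisson_tau1, double poisson_tau2,
                          double dt, double t_total_ms,
                          double field_amp_vm, double field_freq_hz,
                          double field_ton_ms, double field_toff_ms,
                          double field_ramp_ms,
                          int seed, bool shared_poisson,
                          double record_every_ms,
                          double e_na, double e_k, double e_ca,
                          double ca0, double tau_ca, double k_ca,
                          double kd_ca, double refractory_ms) {
  const int nn = neuron_pars.ncol();
  if (neuron_pars.nrow() != NPAR) stop("bad neuron parameter matrix");

  IntegerVector syn_pre = synapses["pre"];
  IntegerVector syn_post = synapses["post"];
  IntegerVector syn_comp = synapses["post_comp"];
  IntegerVector syn_nmda = synapses["is_nmda"];
  NumericVector syn_E = synapses["E"];
  NumericVector syn_tau1 = synapses["tau1"];
  NumericVector syn_tau2 = synapses["tau2"];
  NumericVector syn_w = synapses["w"];
  NumericVector syn_delay = synapses["delay"];
  const int ns = syn_pre.size();

  std::vector<Synapse> syn(ns);
  for (int s = 0; s < ns; ++s) {
    syn[s].post = syn_post[s];
    syn[s].post_comp = syn_comp[s];
    syn[s].is_nmda = syn_nmda[s];
    syn[s].E = syn_E[s];
    syn[s].w = syn_w[s];
    if (syn[s].w < 0) stop("negative synaptic weight");
    syn[s].dec1 = std::exp(-dt / syn_tau1[s]);
    syn[s].dec2 = std::exp(-dt / syn_tau2[s]);
    syn[s].invpeak = dualexp_invpeak(syn_tau1[s], syn_tau2[s]);
    syn[s].R = syn[s].D = 0.0;
  }
  // pending presynaptic events per synapse (times in ms)
  std::vector<std::queue<double>> pending(ns);

  // poisson background synapses, one per neuron, targeting the dendrite
  std::vector<Synapse> psyn(nn);
  std::vector<double> next_poisson(nn, 1e300);
  std::vector<std::mt19937_64> rng(nn);
  for (int i = 0; i < nn; ++i) {
    psyn[i].post = i; psyn[i].post_comp = 1; psyn[i].is_nmda = 0;
    psyn[i].E = 0.0; psyn[i].w = poisson_w[i];
    psyn[i].dec1 = std::exp(-dt / poisson_tau1);
    psyn[i].dec2 = std::exp(-dt / poisson_tau2);
    psyn[i].invpeak = dualexp_invpeak(poisson_tau1, poisson_tau2);
    psyn[i].R = psyn[i].D = 0.0;
    uint64_t sd = shared_poisson
      ? (uint64_t)seed * 2654435761u + 17u
      : ((uint64_t)seed * 2654435761u + 1000003u * (uint64_t)(i + 1));
    rng[i].seed(sd);
    if (poisson_rate[i] > 0) {
      std::exponential_distribution<double> ed(poisson_rate[i] / 1000.0);
      next_poisson[i] = ed(rng[i]);
    }
  }

  // state
  std::vector<double> Vs(nn), Vd(nn);
  std::vector<Gates> g(nn);
  for (int i = 0; i < nn; ++i) {
    double el = neuron_pars(P_EL, i), vt = neuron_pars(P_VT, i);
    Vs[i] = Vd[i] = el;
    double am, bm, ah, bh, an, bn, aq, bq, ar, br;
    na_rates(el, vt, am, bm, ah, bh);
    kv_rates(el, vt, an, bn);
    ca_rates(el, aq, bq, ar, br);
    g[i].m = am / (am + bm); g[i].h = ah / (ah + bh);
    g[i].n = an / (an + bn);
    g[i].p = km_rate(el).inf;
    g[i].q = aq / (aq + bq); g[i].r = ar / (ar + br);
    g[i].ca = ca0;
  }
  std::vector<double> last_spike(nn, -1e300);
  std::vector<std::vector<double>> spikes(nn);

  const int nsteps = (int)std::llround(t_total_ms / dt);
  const int rec_every = record_every_ms > 0
    ? std::max(1, (int)std::llround(record_every_ms / dt)) : 0;
  std::vector<std::vector<double>> recVs, recVd;
  std::vector<double> recT;
  if (rec_every > 0) { recVs.resize(nn); recVd.resize(nn); }

  const double two_pi = 2.0 * M_PI;

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double tnext = t + dt;

    // field envelope and waveform (0 deg = waveform peak at t = ton)
    double E = 0.0;
    if (field_amp_vm > 0 && tnext >= field_ton_ms && tnext <= field_toff_ms) {
      double env = 1.0;
      if (field_ramp_ms > 0) {
        double up = (tnext - field_ton_ms) / field_ramp_ms;
        double dn = (field_toff_ms - tnext) / field_ramp_ms;
        env = std::min(1.0, std::min(up, dn));
        if (env < 0) env = 0;
      }
      E = field_amp_vm * env *
        std::cos(two_pi * field_freq_hz * (tnext - field_ton_ms) / 1000.0);
    }

    // synaptic state decay + delivery of due events
    for (int s = 0; s < ns; ++s) {
      syn[s].R *= syn[s].dec1;
      syn[s].D *= syn[s].dec2;
      while (!pending[s].empty() && pending[s].front() <= t) {
        pending[s].pop();
        syn[s].R += 1.0; syn[s].D += 1.0;
      }
    }
    for (int i = 0; i < nn; ++i) {
      psyn[i].R *= psyn[i].dec1;
      psyn[i].D *= psyn[i].dec2;
      if (poisson_rate[i] > 0) {
        while (next_poisson[i] <= t) {
          psyn[i].R += 1.0; psyn[i].D += 1.0;
          std::exponential_distribution<double> ed(poisson_rate[i] / 1000.0);
          next_poisson[i] += ed(rng[i]);
        }
      }
    }

    // per-neuron: gate update then implicit 2x2 voltage solve
    for (int i = 0; i < nn; ++i) {
      const double vt = neuron_pars(P_VT, i);
      double vs = Vs[i], vd = Vd[i];

      double am, bm, ah, bh, an, bn, aq, bq, ar, br;
      na_rates(vs, vt, am, bm, ah, bh);
      kv_rates(vs, vt, an, bn);
      g[i].m = expEuler(g[i].m, am / (am + bm), 1.0 / (am + bm), dt);
      g[i].h = expEuler(g[i].h, ah / (ah + bh), 1.0 / (ah + bh), dt);
      g[i].n = expEuler(g[i].n, an / (an + bn), 1.0 / (an + bn), dt);
      if (neuron_pars(P_GKM_S, i) > 0) {
        RateOut km = km_rate(vs);
        g[i].p = expEuler(g[i].p, km.inf, km.tau, dt);
      }
      double ica = 0.0;
      if (neuron_pars(P_GCA_S, i) > 0) {
        ca_rates(vs, aq, bq, ar, br);
        g[i].q = expEuler(g[i].q, aq / (aq + bq), 1.0 / (aq + bq), dt);
        g[i].r = expEuler(g[i].r, ar / (ar + br), 1.0 / (ar + br), dt);
        ica = neuron_pars(P_GCA_S, i) * g[i].q * g[i].q * g[i].r *
          (vs - e_ca);
        double ca_inf = ca0 + (ica < 0 ? -k_ca * ica * tau_ca : 0.0);
        g[i].ca = expEuler(g[i].ca, ca_inf, tau_ca, dt);
      }

      // soma conductance terms
      double Gs = 0.0, GsE = 0.0;
      double gna = neuron_pars(P_GNA_S, i) * g[i].m * g[i].m * g[i].m * g[i].h;
      double gkv = neuron_pars(P_GKV_S, i) * std::pow(g[i].n, 4);
      double gkm = neuron_pars(P_GKM_S, i) * g[i].p;
      double gls = neuron_pars(P_GL_S, i);
      double gca = neuron_pars(P_GCA_S, i) * g[i].q * g[i].q * g[i].r;
      double gkca = neuron_pars(P_GKCA_S, i) *
        (g[i].ca / (g[i].ca + kd_ca));
      Gs = gna + gkv + gkm + gls + gca + gkca;
      GsE = gna * e_na + (gkv + gkm + gkca) * e_k + gca * e_ca +
        gls * neuron_pars(P_EL, i);

      // dendrite conductance terms (passive + synaptic + field coupling)
      double Gd = 0.0, GdE = 0.0;
      double gld = neuron_pars(P_GL_D, i);
      Gd = gld;
      GdE = gld * neuron_pars(P_EL, i);

      // synaptic conductances
      for (int s = 0; s < ns; ++s) {
        if (syn[s].post != i) continue;
        double vpost = syn[s].post_comp == 0 ? vs : vd;
        double gg = syn[s].g(vpost);
        if (syn[s].post_comp == 0) { Gs += gg; GsE += gg * syn[s].E; }
        else                       { Gd += gg; GdE += gg * syn[s].E; }
      }
      {
        double gg = psyn[i].g(vd);
        Gd += gg; GdE += gg * psyn[i].E;
      }

      // extracellular potential difference dendrite - soma (mV):
      // Ve = -E . r  =>  Ve_d - Ve_s = -E(t) * pol_um * 1e-3
      double dve = -E * neuron_pars(P_POLUM, i) * 1e-3;

      const double cs = neuron_pars(P_CS, i), cd = neuron_pars(P_CD, i);
      const double gc = neuron_pars(P_GC, i);
      // implicit solve:
      // (cs/dt + Gs + gc) vs' - gc vd' = cs/dt vs + GsE + gc dve + Iinj
      // -gc vs' + (cd/dt + Gd + gc) vd' = cd/dt vd + GdE - gc dve
      double a11 = cs / dt + Gs + gc;
      double a12 = -gc;
      double a21 = -gc;
      double a22 = cd / dt + Gd + gc;
      double b1 = cs / dt * vs + GsE + gc * dve + neuron_pars(P_IINJ, i);
      double b2 = cd / dt * vd + GdE - gc * dve;
      double det = a11 * a22 - a12 * a21;
      double vs_new = (b1 * a22 - a12 * b2) / det;
      double vd_new = (a11 * b2 - a21 * b1) / det;

      if (std::fabs(vs_new) > 200.0 || std::fabs(vd_new) > 200.0 ||
          !std::isfinite(vs_new) || !std::isfinite(vd_new)) {
        stop("numerical divergence (|V| > 200 mV) in neuron %d at t = %f ms",
             i + 1, tnext);
      }

      // somatic spike: upward 0 mV crossing outside the refractory window
      if (vs <= 0.0 && vs_new > 0.0 &&
          tnext - last_spike[i] > refractory_ms) {
        last_spike[i] = tnext;
        spikes[i].push_back(tnext);
        for (int s = 0; s < ns; ++s) {
          if (syn_pre[s] == i) pending[s].push(tnext + syn_delay[s]);
        }
      }
      Vs[i] = vs_new; Vd[i] = vd_new;
    }

    if (rec_every > 0 && step % rec_every == 0) {
      recT.push_back(tnext);
      for (int i = 0; i < nn; ++i) {
        recVs[i].push_back(Vs[i]);
        recVd[i].push_back(Vd[i]);
      }
    }
  }

  List spk(nn), vrec_s(nn), vrec_d(nn);
  for (int i = 0; i < nn; ++i) {
    spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
    if (rec_every > 0) {
      vrec_s[i] = NumericVector(recVs[i].begin(), recVs[i].end());
      vrec_d[i] = NumericVector(recVd[i].begin(), recVd[i].end());
    }
  }
  List out = List::create(_["spike_times_ms"] = spk);
  if (rec_every > 0) {
    out["voltage_t_ms"] = NumericVector(recT.begin(), recT.end());
    out["voltage_soma"] = vrec_s;
    out["voltage_dend"] = vrec_d;
  }
  return out;
}
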