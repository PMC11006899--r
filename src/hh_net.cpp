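#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hodgkin-Huxley two-class (regular-spiking / fast-spiking) network
// integrator. Gates use exponential Euler with per-class lookup tables of
// steady states and decay factors on a 0.05 mV grid; the membrane equation
// uses forward Euler. Synapses are conductance-based single-exponential
// with per-synapse axonal delay handled by circular increment buffers.
// Background drive is an Ornstein-Uhlenbeck current refreshed every
// ou_refresh steps (the OU correlation time is far longer than dt).
// Randomness comes from R's RNG so a set.seed() in the caller fixes the
// raster bit-for-bit for a fixed step size.

struct GateTab {
  std::vector<double> m_inf, m_fac, h_inf, h_fac, n_inf, n_fac, p_inf, p_fac;
};

static const double VMIN = -120.0, VMAX = 60.0, VSTEP = 0.05;

static inline double vtrap(double x, double y) {
  // x / (exp(x / y) - 1) with the removable singularity handled
  return (std::fabs(x / y) < 1e-6) ? y * (1.0 - x / y / 2.0)
                                   : x / (std::exp(x / y) - 1.0);
}

static GateTab build_tab(double VT, double tau_max_p, double dt) {
  int n = (int)((VMAX - VMIN) / VSTEP) + 2;
  GateTab tb;
  tb.m_inf.resize(n); tb.m_fac.resize(n);
  tb.h_inf.resize(n); tb.h_fac.resize(n);
  tb.n_inf.resize(n); tb.n_fac.resize(n);
  tb.p_inf.resize(n); tb.p_fac.resize(n);
  for (int i = 0; i < n; ++i) {
    double V = VMIN + i * VSTEP;
    // Traub-type kinetics, e.g. am = -0.32 (V-VT-13)/(exp(-(V-VT-13)/4)-1)
    double am = 0.32 * vtrap(-(V - VT - 13.0), 4.0);
    double bm = 0.28 * vtrap(V - VT - 40.0, 5.0);
    double ah = 0.128 * std::exp(-(V - VT - 17.0) / 18.0);
    double bh = 4.0 / (1.0 + std::exp(-(V - VT - 40.0) / 5.0));
    double an = 0.032 * vtrap(-(V - VT - 15.0), 5.0);
    double bn = 0.5 * std::exp(-(V - VT - 10.0) / 40.0);
    double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh), tn = 1.0 / (an + bn);
    tb.m_inf[i] = am * tm; tb.m_fac[i] = std::exp(-dt / tm);
    tb.h_inf[i] = ah * th; tb.h_fac[i] = std::exp(-dt / th);
    tb.n_inf[i] = an * tn; tb.n_fac[i] = std::exp(-dt / tn);
    // slow non-inactivating K+ (adaptation) gate
    double pinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
    double tp = tau_max_p /
      (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
    tb.p_inf[i] = pinf; tb.p_fac[i] = std::exp(-dt / tp);
  }
  return tb;
}

static inline int vidx(double V) {
  if (V < VMIN) V = VMIN;
  if (V > VMAX) V = VMAX;
  return (int)((V - VMIN) / VSTEP);
}

// [[Rcpp::export(name = ".hh_simulate_cpp")]]
List hh_simulate_cpp(int n_neurons,
                     IntegerVector cls,          // 0 = RS, 1 = FS
                     NumericMatrix class_par,    // 2 x 10 parameter rows
                     IntegerVector syn_pre, IntegerVector syn_post,
                     NumericVector syn_w,        // mS/cm^2 increment
                     IntegerVector syn_delay,    // steps
                     IntegerVector syn_inh,      // 0 exc / 1 inh
                     IntegerVector syn_inter,    // 1 = inter-population
                     double duration_ms, double dt,
                     NumericVector ou_mu,        // uA/cm^2 per neuron
                     double ou_sigma, double ou_tau_ms, int ou_refresh,
                     NumericMatrix protocol,     // rows: t0,t1,type,freq,width,amp
                     IntegerVector pulse_target, // 1 = receives pulse drive
                     IntegerVector record_idx,   // 0-based, V traces
                     int record_stride) {
  const int nsteps = (int)(duration_ms / dt);
  const double tau_e = 5.0, tau_i = 10.0;   // ms
  const double E_e = 0.0, E_i = -80.0, E_na = 50.0, E_k = -90.0;
  const double dec_e = std::exp(-dt / tau_e), dec_i = std::exp(-dt / tau_i);

  // class parameter order: Cm gL EL gNa gK gM VT tau_max refr_ms v_init
  GateTab tabs[2] = {
    build_tab(class_par(0, 6), class_par(0, 7), dt),
    build_tab(class_par(1, 6), class_par(1, 7), dt)
  };

  std::vector<double> V(n_neurons), m(n_neurons), h(n_neurons),
      nn(n_neurons), p(n_neurons), ge(n_neurons, 0.0), gi(n_neurons, 0.0),
      iou(n_neurons, 0.0);
  for (int i = 0; i < n_neurons; ++i) {
    int c = cls[i];
    V[i] = class_par(c, 9);
    int k = vidx(V[i]);
    m[i] = tabs[c].m_inf[k]; h[i] = tabs[c].h_inf[k];
    nn[i] = tabs[c].n_inf[k]; p[i] = tabs[c].p_inf[k];
    iou[i] = ou_mu[i];
  }

  // CSR outgoing synapse index by presynaptic neuron
  int nsyn = syn_pre.size();
  std::vector<int> off(n_neurons + 1, 0);
  for (int s = 0; s < nsyn; ++s) off[syn_pre[s] + 1]++;
  for (int i = 0; i < n_neurons; ++i) off[i + 1] += off[i];
  std::vector<int> order(nsyn);
  { std::vector<int> cur(off.begin(), off.end() - 1);
    for (int s = 0; s < nsyn; ++s) order[cur[syn_pre[s]]++] = s; }

  int maxd = 1;
  for (int s = 0; s < nsyn; ++s) if (syn_delay[s] + 1 > maxd)
    maxd = syn_delay[s] + 1;
  std::vector<double> buf_e((size_t)maxd * n_neurons, 0.0);
  std::vector<double> buf_i((size_t)maxd * n_neurons, 0.0);

  std::vector<int> spk_id; std::vector<double> spk_t;
  std::vector<char> above(n_neurons, 0);

  int nrec = record_idx.size();
  int nrow_tr = nrec > 0 ? ((nsteps - 1) / record_stride + 1) : 0;
  NumericMatrix traces(nrow_tr, nrec);
  NumericVector trace_t(nrow_tr);

  const double ou_a = std::exp(-(dt * ou_refresh) / ou_tau_ms);
  const double ou_b = ou_sigma * std::sqrt(1.0 - ou_a * ou_a);

  int nprot = protocol.nrow();
  double sq_dt = dt; (void)sq_dt;
  int trow = 0;
  bool diverged = false; int div_step = -1;

  for (int step = 0; step < nsteps; ++step) {
    double t_ms = step * dt;
    // protocol state
    bool inter_on = true;
    double pulse_amp = 0.0;
    for (int e = 0; e < nprot; ++e) {
      if (t_ms >= protocol(e, 0) && t_ms < protocol(e, 1)) {
        if (protocol(e, 2) == 1.0) inter_on = false;     // silence_inter
        else if (protocol(e, 2) == 2.0) {                // periodic pulses
          double per = 1000.0 / protocol(e, 3);
          double el = t_ms - protocol(e, 0);
          double ph = el - std::floor(el / per) * per;
          if (ph < protocol(e, 4)) pulse_amp = protocol(e, 5);
        }
      }
    }
    // OU refresh
    if (step % ou_refresh == 0) {
      for (int i = 0; i < n_neurons; ++i)
        iou[i] = ou_mu[i] + (iou[i] - ou_mu[i]) * ou_a + ou_b * norm_rand();
    }
    int slot = step % maxd;
    double *be = &buf_e[(size_t)slot * n_neurons];
    double *bi = &buf_i[(size_t)slot * n_neurons];
    for (int i = 0; i < n_neurons; ++i) {
      ge[i] = ge[i] * dec_e + be[i];
      gi[i] = gi[i] * dec_i + bi[i];
      be[i] = 0.0; bi[i] = 0.0;
    }
    for (int i = 0; i < n_neurons; ++i) {
      int c = cls[i];
      const GateTab &tb = tabs[c];
      int k = vidx(V[i]);
      m[i] = tb.m_inf[k] + (m[i] - tb.m_inf[k]) * tb.m_fac[k];
      h[i] = tb.h_inf[k] + (h[i] - tb.h_inf[k]) * tb.h_fac[k];
      nn[i] = tb.n_inf[k] + (nn[i] - tb.n_inf[k]) * tb.n_fac[k];
      double gM = class_par(c, 5);
      if (gM > 0.0)
        p[i] = tb.p_inf[k] + (p[i] - tb.p_inf[k]) * tb.p_fac[k];
      double m3h = m[i] * m[i] * m[i] * h[i];
      double n4 = nn[i] * nn[i]; n4 *= n4;
      double I_inj = iou[i] + (pulse_target[i] ? pulse_amp : 0.0);
      double dV = (-class_par(c, 1) * (V[i] - class_par(c, 2))
                   - class_par(c, 3) * m3h * (V[i] - E_na)
                   - class_par(c, 4) * n4 * (V[i] - E_k)
                   - gM * p[i] * (V[i] - E_k)
                   - ge[i] * (V[i] - E_e)
                   - gi[i] * (V[i] - E_i)
                   + I_inj) / class_par(c, 0);
      V[i] += dt * dV;
      if (V[i] > 200.0 || V[i] < -200.0 || !std::isfinite(V[i])) {
        diverged = true; div_step = step; break;
      }
      // spike on upward crossing of -10 mV; re-arm below -30 mV
      if (!above[i] && V[i] > -10.0) {
        above[i] = 1;
        spk_id.push_back(i);
        spk_t.push_back(t_ms + dt);
        for (int q = off[i]; q < off[i + 1]; ++q) {
          int s = order[q];
          if (!inter_on && syn_inter[s]) continue;
          int dst = (step + syn_delay[s]) % maxd;
          double *tgt = syn_inh[s] ? &buf_i[(size_t)dst * n_neurons]
                                   : &buf_e[(size_t)dst * n_neurons];
          tgt[syn_post[s]] += syn_w[s];
        }
      } else if (above[i] && V[i] < -30.0) {
        above[i] = 0;
      }
    }
    if (diverged) break;
    if (nrec > 0 && step % record_stride == 0 && trow < nrow_tr) {
      for (int r = 0; r < nrec; ++r) traces(trow, r) = V[record_idx[r]];
      trace_t[trow] = t_ms;
      ++trow;
    }
  }

  return List::create(
    _["spike_neuron"] = IntegerVector(spk_id.begin(), spk_id.end()),
    _["spike_time_ms"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["traces"] = traces, _["trace_t_ms"] = trace_t,
    _["diverged"] = diverged, _["diverged_step"] = div_step);
}
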