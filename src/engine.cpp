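// Fixed-step integrator for the single-compartment MSN model and the
// recurrent inhibitory network with Tsodyks-Markram depressing/facilitating
// GABA synapses.
//
// Units: mV, ms, mS/cm^2, uA/cm^2, uF/cm^2 (C = 1).  Gating variables are
// advanced by exponential Euler using voltage lookup tables rebuilt for each
// (params, dt) pair, in the manner of NEURON's TABLE mechanisms; the membrane
// equation uses the exact exponential update for piecewise-constant
// conductances.  All state updates are deterministic: no RNG lives here.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(x)); }

// Voltage grid for gating tables.
static const double V_LO = -130.0;
static const double V_HI = 60.0;
static const double V_STEP = 0.05;
static const int NTAB = (int)((V_HI - V_LO) / V_STEP) + 2;

struct CellKin {
  // conductances and reversal potentials
  double gL, EL, gNa, ENa, gK, EK, gKir, gAf, gAs, gKrp, gNaP, gNaS;
  double kir_vh, kir_k;
  double drive_scale, syn_scale;
  // tables: steady states and per-dt decay factors
  std::vector<double> m3, hinf, hdec, ninf, ndec, kir, af, bfinf, asinf, bsinf,
      krpinf, napinf, nasinf;
  double bf_dec, as_dec, bs_dec, krp_dec, nas_dec;

  void build(const NumericVector& p, double dt) {
    gL = p["g_l"];      EL = p["e_l"];
    gNa = p["g_na"];    ENa = p["e_na"];
    gK = p["g_k"];      EK = p["e_k"];
    gKir = p["g_kir"];  gAf = p["g_af"];  gAs = p["g_as"];
    gKrp = p["g_krp"];  gNaP = p["g_nap"]; gNaS = p["g_nas"];
    kir_vh = p["kir_vh"]; kir_k = p["kir_k"];
    drive_scale = p["drive_scale"];
    syn_scale = p["syn_scale"];

    const double m_vh = p["m_vh"], m_k = p["m_k"];
    const double h_vh = p["h_vh"], h_k = p["h_k"];
    const double tau_h0 = p["tau_h0"], tau_h1 = p["tau_h1"],
                 tau_h_vh = p["tau_h_vh"], tau_h_k = p["tau_h_k"];
    const double n_vh = p["n_vh"], n_k = p["n_k"];
    const double tau_n0 = p["tau_n0"], tau_n1 = p["tau_n1"],
                 tau_n_vh = p["tau_n_vh"], tau_n_k = p["tau_n_k"];
    const double af_vh = p["af_vh"], af_k = p["af_k"];
    const double bf_vh = p["bf_vh"], bf_k = p["bf_k"];
    const double as_vh = p["as_vh"], as_k = p["as_k"];
    const double bs_vh = p["bs_vh"], bs_k = p["bs_k"], bs_min = p["bs_min"];
    const double krp_vh = p["krp_vh"], krp_k = p["krp_k"];
    const double nap_vh = p["nap_vh"], nap_k = p["nap_k"];
    const double nas_vh = p["nas_vh"], nas_k = p["nas_k"];

    m3.resize(NTAB); hinf.resize(NTAB); hdec.resize(NTAB);
    ninf.resize(NTAB); ndec.resize(NTAB); kir.resize(NTAB);
    af.resize(NTAB); bfinf.resize(NTAB); asinf.resize(NTAB);
    bsinf.resize(NTAB); krpinf.resize(NTAB); napinf.resize(NTAB);
    nasinf.resize(NTAB);

    for (int i = 0; i < NTAB; i++) {
      double V = V_LO + i * V_STEP;
      double m = sig(-(V - m_vh) / m_k);
      m3[i] = m * m * m;
      hinf[i] = sig((V - h_vh) / h_k);
      double tau_h = tau_h0 + tau_h1 * sig((V - tau_h_vh) / tau_h_k);
      hdec[i] = std::exp(-dt / tau_h);
      ninf[i] = sig(-(V - n_vh) / n_k);
      double tau_n = tau_n0 + tau_n1 * sig((V - tau_n_vh) / tau_n_k);
      ndec[i] = std::exp(-dt / tau_n);
      kir[i] = sig((V - kir_vh) / kir_k);
      af[i] = sig(-(V - af_vh) / af_k);
      bfinf[i] = sig((V - bf_vh) / bf_k);
      asinf[i] = sig(-(V - as_vh) / as_k);
      bsinf[i] = bs_min + (1.0 - bs_min) * sig((V - bs_vh) / bs_k);
      krpinf[i] = sig(-(V - krp_vh) / krp_k);
      napinf[i] = sig(-(V - nap_vh) / nap_k);
      nasinf[i] = sig(-(V - nas_vh) / nas_k);
    }
    bf_dec = std::exp(-dt / (double)p["tau_bf"]);
    as_dec = std::exp(-dt / (double)p["tau_as"]);
    bs_dec = std::exp(-dt / (double)p["tau_bs"]);
    krp_dec = std::exp(-dt / (double)p["tau_krp"]);
    nas_dec = std::exp(-dt / (double)p["tau_nas"]);
  }

  inline int idx(double V) const {
    int i = (int)((V - V_LO) / V_STEP);
    if (i < 0) i = 0;
    if (i >= NTAB) i = NTAB - 1;
    return i;
  }
};

struct CellState {
  double V, h, n, bf, as_, bs, krp, nas;
};

// One exponential-Euler step for one cell; returns new V.
static inline void step_cell(const CellKin& K, CellState& s, double I_ext,
                             double g_syn, double E_syn, double dt) {
  int i = K.idx(s.V);
  // gating updates (tabled steady states / decays)
  s.h = K.hinf[i] + (s.h - K.hinf[i]) * K.hdec[i];
  s.n = K.ninf[i] + (s.n - K.ninf[i]) * K.ndec[i];
  s.bf = K.bfinf[i] + (s.bf - K.bfinf[i]) * K.bf_dec;
  s.as_ = K.asinf[i] + (s.as_ - K.asinf[i]) * K.as_dec;
  s.bs = K.bsinf[i] + (s.bs - K.bsinf[i]) * K.bs_dec;
  s.krp = K.krpinf[i] + (s.krp - K.krpinf[i]) * K.krp_dec;
  s.nas = K.nasinf[i] + (s.nas - K.nasinf[i]) * K.nas_dec;

  double gna = K.gNa * K.m3[i] * s.h;
  double gk = K.gK * s.n * s.n;
  double gkir = K.gKir * K.kir[i];
  double gaf = K.gAf * K.af[i] * s.bf;
  double gas = K.gAs * s.as_ * s.bs;
  double gkrp = K.gKrp * s.krp;
  double gnap = K.gNaP * K.napinf[i];
  double gnas = K.gNaS * s.nas;

  double gtot = K.gL + gna + gk + gkir + gaf + gas + gkrp + gnap + gnas + g_syn;
  double gE = K.gL * K.EL + (gna + gnap + gnas) * K.ENa +
              (gk + gkir + gaf + gas + gkrp) * K.EK + g_syn * E_syn;
  double Vinf = (gE + I_ext) / gtot;
  s.V = Vinf + (s.V - Vinf) * std::exp(-dt * gtot); // C = 1 uF/cm^2
}

static CellState rest_state(const CellKin& K, double I_hold, double settle_ms,
                            double dt) {
  CellState s;
  s.V = -80.0;
  int i = K.idx(s.V);
  s.h = K.hinf[i]; s.n = K.ninf[i]; s.bf = K.bfinf[i]; s.as_ = K.asinf[i];
  s.bs = K.bsinf[i]; s.krp = K.krpinf[i]; s.nas = K.nasinf[i];
  long nsteps = (long)std::ceil(settle_ms / dt);
  for (long t = 0; t < nsteps; t++) step_cell(K, s, I_hold, 0.0, 0.0, dt);
  return s;
}

// Core engine.  Cells are identical; the network structure is an edge list
// with per-edge weight (raw conductance units summed into the target's
// synaptic conductance after scaling by syn_scale) and delay in steps.
// External inhibitory events (the IPSP characterization protocol) are
// delivered to cell `ext_target` through their own TM state.
// [[Rcpp::export]]
List cpp_engine(NumericVector params, int n_cells, IntegerVector e_src,
                IntegerVector e_dst, NumericVector e_w, IntegerVector e_dsteps,
                NumericVector drives, double duration_ms, double dt,
                double settle_ms, double hold_current,
                NumericVector ext_times, double ext_weight, int ext_target,
                double e_syn, double tm_u, double tm_d, double tm_f,
                double tau_syn, bool record_trace, int record_cell,
                int record_every) {
  CellKin K;
  K.build(params, dt);

  const int N = n_cells;
  const long nsteps = (long)std::ceil(duration_ms / dt);

  // settle once from rest (all cells identical), then copy
  CellState s0 = rest_state(K, hold_current, settle_ms, dt);
  std::vector<CellState> cells(N, s0);
  std::vector<double> prevV(N, s0.V);
  std::vector<double> last_spike(N, -1e18);

  // per-cell external current
  std::vector<double> I_ext(N);
  for (int i = 0; i < N; i++)
    I_ext[i] = hold_current + K.drive_scale * (drives.size() > 0 ? drives[i % drives.size()] : 0.0);

  // adjacency as CSR over source cells
  int n_edges = e_src.size();
  std::vector<int> deg(N, 0);
  for (int e = 0; e < n_edges; e++) deg[e_src[e]]++;
  std::vector<int> ptr(N + 1, 0);
  for (int i = 0; i < N; i++) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj_dst(n_edges);
  std::vector<double> adj_w(n_edges);
  std::vector<int> adj_d(n_edges);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < n_edges; e++) {
      int s = e_src[e];
      adj_dst[fill[s]] = e_dst[e];
      adj_w[fill[s]] = e_w[e];
      adj_d[fill[s]] = e_dsteps[e];
      fill[s]++;
    }
  }

  // TM state per presynaptic cell (identical spike train -> identical state
  // across that cell's synapses), advanced lazily at its spike times.
  std::vector<double> tmR(N, 1.0), tmS(N, 0.0), tm_last(N, 0.0);
  double extR = 1.0, extS = 0.0, ext_last = 0.0;

  // delayed-delivery ring buffer of conductance increments
  int max_d = 1;
  for (int e = 0; e < n_edges; e++) if (adj_d[e] + 1 > max_d) max_d = adj_d[e] + 1;
  std::vector<double> ring((size_t)max_d * N, 0.0);

  // external events in step units
  std::vector<long> ext_steps(ext_times.size());
  for (int i = 0; i < ext_times.size(); i++)
    ext_steps[i] = (long)std::llround(ext_times[i] / dt);
  size_t ext_ptr = 0;

  std::vector<double> g_syn(N, 0.0);
  double syn_dec = std::exp(-dt / tau_syn);

  std::vector<int> sp_cell;
  std::vector<double> sp_time;

  std::vector<double> tr_t, tr_v;
  if (record_trace) {
    tr_t.reserve(nsteps / record_every + 2);
    tr_v.reserve(nsteps / record_every + 2);
    tr_t.push_back(0.0);
    tr_v.push_back(cells[record_cell].V);
  }

  for (long st = 0; st < nsteps; st++) {
    double t = (st + 1) * dt;
    int slot = (int)(st % max_d);

    // deliver external inhibitory events scheduled for this step
    while (ext_ptr < ext_steps.size() && ext_steps[ext_ptr] == st) {
      double tev = ext_steps[ext_ptr] * dt;
      double dtr = tev - ext_last;
      if (dtr > 0) {
        extR = 1.0 + (extR - 1.0) * std::exp(-dtr / tm_d);
        extS = extS * std::exp(-dtr / tm_f);
      }
      double Spost = extS + tm_u * (1.0 - extS);
      double inc = ext_weight * extR * Spost;
      extR = extR * (1.0 - Spost);
      extS = Spost;
      ext_last = tev;
      g_syn[ext_target] += inc;
      ext_ptr++;
    }

    // integrate all cells with conductances frozen over the step
    for (int i = 0; i < N; i++) {
      double* rb = &ring[(size_t)slot * N];
      if (rb[i] != 0.0) { g_syn[i] += rb[i]; rb[i] = 0.0; }
      prevV[i] = cells[i].V;
      step_cell(K, cells[i], I_ext[i], K.syn_scale * g_syn[i], e_syn, dt);
      g_syn[i] *= syn_dec;
    }

    // spike detection: upward crossing of 0 mV, 2 ms lockout
    for (int i = 0; i < N; i++) {
      if (prevV[i] < 0.0 && cells[i].V >= 0.0 && t - last_spike[i] >= 2.0) {
        last_spike[i] = t;
        sp_cell.push_back(i);
        sp_time.push_back(t);
        // TM update and delayed delivery on out-edges
        if (ptr[i + 1] > ptr[i]) {
          double dtr = t - tm_last[i];
          if (dtr > 0) {
            tmR[i] = 1.0 + (tmR[i] - 1.0) * std::exp(-dtr / tm_d);
            tmS[i] = tmS[i] * std::exp(-dtr / tm_f);
          }
          double Spost = tmS[i] + tm_u * (1.0 - tmS[i]);
          double eff = tmR[i] * Spost;
          tmR[i] = tmR[i] * (1.0 - Spost);
          tmS[i] = Spost;
          tm_last[i] = t;
          for (int e = ptr[i]; e < ptr[i + 1]; e++) {
            int dslot = (int)((st + adj_d[e]) % max_d);
            ring[(size_t)dslot * N + adj_dst[e]] += adj_w[e] * eff;
          }
        }
      }
    }

    if (record_trace && ((st + 1) % record_every == 0)) {
      tr_t.push_back(t);
      tr_v.push_back(cells[record_cell].V);
    }

    if ((st & 0x3FF) == 0) {
      for (int i = 0; i < N; i++) {
        if (!std::isfinite(cells[i].V))
          stop("integration failure: non-finite membrane potential, cell %d at t = %.3f ms",
               i + 1, t);
      }
    }
  }
  for (int i = 0; i < N; i++)
    if (!std::isfinite(cells[i].V))
      stop("integration failure: non-finite membrane potential, cell %d at end of run", i + 1);

  List out = List::create(
      _["spike_cell"] = wrap(sp_cell), _["spike_time"] = wrap(sp_time),
      _["v_end"] = cells[record_cell].V);
  if (record_trace) {
    out["time"] = wrap(tr_t);
    out["v"] = wrap(tr_v);
  }
  return out;
}

// Holding current that clamps the steady state at v_hold (closed form: all
// gating variables take their steady-state values at v_hold).
// [[Rcpp::export]]
double cpp_holding_current(NumericVector params, double v_hold) {
  CellKin K;
  K.build(params, 0.025);
  int i = K.idx(v_hold);
  double gna = K.gNa * K.m3[i] * K.hinf[i];
  double gk = K.gK * K.ninf[i] * K.ninf[i];
  double gkir = K.gKir * K.kir[i];
  double gaf = K.gAf * K.af[i] * K.bfinf[i];
  double gas = K.gAs * K.asinf[i] * K.bsinf[i];
  double gkrp = K.gKrp * K.krpinf[i];
  double gnap = K.gNaP * K.napinf[i];
  double gnas = K.gNaS * K.nasinf[i];
  double gtot = K.gL + gna + gk + gkir + gaf + gas + gkrp + gnap + gnas;
  double gE = K.gL * K.EL + (gna + gnap + gnas) * K.ENa +
              (gk + gkir + gaf + gas + gkrp) * K.EK;
  return v_hold * gtot - gE;
}
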