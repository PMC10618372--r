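#include <Rcpp.h>
using namespace Rcpp;

// Stochastic single-compartment PVN neurone.
//
// Deterministic Hodgkin-Huxley spike machinery plus stochastic channel
// populations (delayed-rectifier Kv, Trpv4-like, Trpm2-like, SK), a
// TRP->SK Ca2+ microdomain (two-compartment buffered exchange with the
// bulk cytosol), and Poisson synaptic drive with an inhibitory
// interneurone stage. Fixed-step Euler integration of the membrane
// equation (dt <= 0.025 ms); channel populations are updated on a
// coarser substep with per-transition binomial draws from R's RNG, so a
// run is reproducible under set.seed().
//
// Units: ms, mV, pA, nS, pF, uM, L.

static inline double safe_exp_ratio(double x, double y) {
  // x / (exp(x / y) - 1), stable near x = 0
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - r / 2.0);
  return x / (std::exp(r) - 1.0);
}

// sequential conditional binomial thinning of a state's occupancy over
// its outgoing transitions (conserves channel number exactly)
static void step_population(std::vector<int>& n, const NumericMatrix& Q,
                            double dtc) {
  const int k = n.size();
  std::vector<int> delta(k, 0);
  for (int i = 0; i < k; ++i) {
    if (n[i] == 0) continue;
    int rem = n[i];
    double pleft = 1.0;
    for (int j = 0; j < k && rem > 0; ++j) {
      if (j == i) continue;
      double p = Q(i, j) * dtc;
      if (p <= 0.0) continue;
      double pc = p / pleft;
      if (pc > 1.0) pc = 1.0;
      int m = (int)R::rbinom((double)rem, pc);
      delta[i] -= m;
      delta[j] += m;
      rem -= m;
      pleft -= p;
      if (pleft <= 0.0) break;
    }
  }
  for (int i = 0; i < k; ++i) n[i] += delta[i];
}

// GHK-based fraction of a TRP channel's current carried by Ca2+, as a
// function of voltage, for a given PCa/PNa permeability ratio.
static double ca_fraction(double v, double pca_rel) {
  const double RTF = 26.73;  // mV at 37 C (fixed; not a thermosensor)
  const double nao = 140.0, nai = 12.0;   // mM
  const double cao = 2.0, cai = 1e-4;     // mM
  double u1 = v / RTF;
  double u2 = 2.0 * v / RTF;
  double ina, ica;
  if (std::fabs(u1) < 1e-9) {
    ina = (nai - nao);
  } else {
    ina = u1 * (nai - nao * std::exp(-u1)) / (1.0 - std::exp(-u1));
  }
  if (std::fabs(u2) < 1e-9) {
    ica = 4.0 * pca_rel * (cai - cao);
  } else {
    ica = 4.0 * pca_rel * u2 * (cai - cao * std::exp(-u2)) /
          (1.0 - std::exp(-u2));
  }
  double denom = std::fabs(ina) + std::fabs(ica);
  if (denom <= 0.0) return 0.0;
  return std::fabs(ica) / denom;
}

// [[Rcpp::export(name = ".neuron_sim")]]
List neuron_sim(List par) {
  const double dt = par["dt"];
  const int n_steps = par["n_steps"];
  const int ch_every = par["channel_every"];
  const int rec_every = par["record_every"];

  const double C = par["capacitance"], gL = par["g_leak"], EL = par["e_leak"];
  const double gNa = par["g_na"], ENa = par["e_na"];
  const double gKhh = par["g_k"], EK = par["e_k"];

  // Kv population (5-state n^4 chain)
  const int n_kv = par["n_kv"];
  const double gkv = par["gamma_kv"];

  // TRP populations: fixed generators (temperature applied upstream)
  const NumericMatrix Qv4 = par["q_trpv4"];
  const LogicalVector openv4 = par["open_trpv4"];
  const int n_v4 = par["n_trpv4"];
  const double gv4 = par["gamma_trpv4"], ev4 = par["e_trpv4"];
  const double pca_v4 = par["pca_trpv4"];
  const IntegerVector initv4 = par["init_trpv4"];

  const NumericMatrix Qm2 = par["q_trpm2"];
  const LogicalVector openm2 = par["open_trpm2"];
  const int n_m2 = par["n_trpm2"];
  const double gm2 = par["gamma_trpm2"], em2 = par["e_trpm2"];
  const double pca_m2 = par["pca_trpm2"];
  const IntegerVector initm2 = par["init_trpm2"];

  // SK population (Moczydlowski-Latorre Ca/V-dependent two-state)
  const int n_sk = par["n_sk"];
  const double gsk = par["gamma_sk"];
  const double sk_abar = par["sk_abar"], sk_bbar = par["sk_bbar"];
  const double sk_k1 = par["sk_k1"], sk_d1 = par["sk_d1"];
  const double sk_k2 = par["sk_k2"], sk_d2 = par["sk_d2"];

  // microdomain / bulk Ca2+
  const double ca_per_pA = par["ca_per_pA"];   // uM/ms per pA into domain
  const double buffer_div = par["buffer_div"]; // 1 + buffer capacity
  const double k_md = par["k_md"];             // domain-bulk exchange, 1/ms
  const double vol_ratio = par["vol_ratio"];   // domain/bulk effective vol
  const double tau_bulk = par["tau_bulk"];     // bulk extrusion, ms
  const double ca_rest = par["ca_rest"];       // uM

  // synaptic drive
  const double rate_e = par["rate_e"];     // Hz
  const double w_e = par["w_e"], tau_e = par["tau_e"];
  const double rate_id = par["rate_inh_drive"]; // Hz onto interneurone
  const double inh_gain = par["inh_gain"], inh_theta = par["inh_theta"];
  const double w_i = par["w_i"], tau_i = par["tau_i"], E_i = par["e_i"];
  const double tau_s = par["tau_s"];

  const double v_thr = par["spike_threshold"];
  const double refrac = par["refractory"];

  double V = par["v_init"];
  double m = 0.05, h = 0.6, ng = 0.32;
  double ca_md = ca_rest, ca_bulk = ca_rest;
  double g_e = 0.0, g_i = 0.0, s_int = 0.0;

  std::vector<int> nv4(initv4.begin(), initv4.end());
  std::vector<int> nm2(initm2.begin(), initm2.end());
  std::vector<int> nkv(5, 0);
  std::vector<int> nsk(2, 0);
  nsk[0] = n_sk;
  {
    // Kv initial occupancy from the resting n-gate open fraction
    double vs = V + 65.0;
    double an = 0.01 * safe_exp_ratio(10.0 - vs, 10.0);
    double bn = 0.125 * std::exp(-vs / 80.0);
    double p = an / (an + bn);
    for (int i = 0; i < n_kv; ++i) {
      int k = 0;
      for (int g = 0; g < 4; ++g) if (R::unif_rand() < p) ++k;
      nkv[k] += 1;
    }
  }

  const double dec_e = std::exp(-dt / tau_e);
  const double dec_i = std::exp(-dt / tau_i);
  const double dec_s = std::exp(-dt / tau_s);
  const double dtc = dt * ch_every;

  std::vector<double> spikes;
  double last_spike = -1e9;
  bool above = false;

  const int n_rec = n_steps / rec_every + 1;
  NumericVector rec_t(n_rec), rec_v(n_rec), rec_camd(n_rec), rec_cab(n_rec);
  NumericVector rec_sk(n_rec), rec_v4(n_rec), rec_m2(n_rec);
  int ir = 0;

  NumericMatrix Qkv(5, 5), Qsk(2, 2);
  bool aborted = false;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    if (step % ch_every == 0) {
      // voltage/Ca-dependent generators refreshed on the channel substep
      double vs = V + 65.0;
      double an = 0.01 * safe_exp_ratio(10.0 - vs, 10.0);
      double bn = 0.125 * std::exp(-vs / 80.0);
      for (int i = 0; i < 5; ++i)
        for (int j = 0; j < 5; ++j) Qkv(i, j) = 0.0;
      for (int i = 0; i < 4; ++i) {
        Qkv(i, i + 1) = (4 - i) * an;
        Qkv(i + 1, i) = (i + 1) * bn;
      }
      if (n_kv > 0) step_population(nkv, Qkv, dtc);

      if (n_v4 > 0) step_population(nv4, Qv4, dtc);
      if (n_m2 > 0) step_population(nm2, Qm2, dtc);

      // Moczydlowski-Latorre rates at fixed 37 C thermal energy
      const double vfac = 9.648e4 / (8.315 * 310.15) * 1e-3; // 1/mV
      double k1eff = sk_k1 * std::exp(-2.0 * sk_d1 * vfac * V); // mM
      double k2eff = sk_k2 * std::exp(-2.0 * sk_d2 * vfac * V); // mM
      double ca_mM = ca_md * 1e-3;
      double alp = sk_abar / (1.0 + k1eff / ca_mM);
      double bet = sk_bbar / (1.0 + ca_mM / k2eff);
      Qsk(0, 1) = alp;
      Qsk(1, 0) = bet;
      if (n_sk > 0) step_population(nsk, Qsk, dtc);
    }

    // synaptic events
    int ne = (int)R::rpois(rate_e * dt * 1e-3);
    if (ne > 0) g_e += ne * w_e;
    int nid = (int)R::rpois(rate_id * dt * 1e-3);
    if (nid > 0) s_int += nid;
    double r_inh = inh_gain * (s_int - inh_theta);
    if (r_inh > 0.0) {
      int ni = (int)R::rpois(r_inh * dt * 1e-3);
      if (ni > 0) g_i += ni * w_i;
    }
    g_e *= dec_e;
    g_i *= dec_i;
    s_int *= dec_s;

    // open counts
    int ov4 = 0, om2 = 0;
    for (int i = 0; i < (int)nv4.size(); ++i) if (openv4[i]) ov4 += nv4[i];
    for (int i = 0; i < (int)nm2.size(); ++i) if (openm2[i]) om2 += nm2[i];
    int okv = nkv[4];
    int osk = nsk[1];

    // membrane currents (pA)
    double vs = V + 65.0;
    double am = 0.1 * safe_exp_ratio(25.0 - vs, 10.0);
    double bm = 4.0 * std::exp(-vs / 18.0);
    double ah = 0.07 * std::exp(-vs / 20.0);
    double bh = 1.0 / (std::exp((30.0 - vs) / 10.0) + 1.0);
    double an = 0.01 * safe_exp_ratio(10.0 - vs, 10.0);
    double bn = 0.125 * std::exp(-vs / 80.0);
    m += dt * (am * (1.0 - m) - bm * m);
    h += dt * (ah * (1.0 - h) - bh * h);
    ng += dt * (an * (1.0 - ng) - bn * ng);
    if (m < 0) m = 0; if (m > 1) m = 1;
    if (h < 0) h = 0; if (h > 1) h = 1;
    if (ng < 0) ng = 0; if (ng > 1) ng = 1;

    double I_L = gL * (V - EL);
    double I_Na = gNa * m * m * m * h * (V - ENa);
    double I_K = gKhh * ng * ng * ng * ng * (V - EK);
    double I_kv = gkv * okv * (V - EK);
    double I_v4 = gv4 * ov4 * (V - ev4);
    double I_m2 = gm2 * om2 * (V - em2);
    double I_sk = gsk * osk * (V - EK);
    double I_syn = g_e * (V - 0.0) + g_i * (V - E_i);

    // Ca2+ entering the microdomain through open TRP channels (inward only)
    double I_ca = 0.0;
    if (ov4 > 0 && V < ev4) I_ca += ca_fraction(V, pca_v4) * gv4 * ov4 * (V - ev4);
    if (om2 > 0 && V < em2) I_ca += ca_fraction(V, pca_m2) * gm2 * om2 * (V - em2);

    ca_md += dt * (-I_ca * ca_per_pA / buffer_div - k_md * (ca_md - ca_bulk));
    ca_bulk += dt * (k_md * (ca_md - ca_bulk) * vol_ratio -
                     (ca_bulk - ca_rest) / tau_bulk);
    if (ca_md < 1e-6) ca_md = 1e-6;
    if (ca_bulk < 1e-6) ca_bulk = 1e-6;

    V += -dt * (I_L + I_Na + I_K + I_kv + I_v4 + I_m2 + I_sk + I_syn) / C;

    if (step % rec_every == 0 && ir < n_rec) {
      rec_t[ir] = t; rec_v[ir] = V; rec_camd[ir] = ca_md; rec_cab[ir] = ca_bulk;
      rec_sk[ir] = osk; rec_v4[ir] = ov4; rec_m2[ir] = om2;
      ++ir;
    }

    if (!std::isfinite(V) || std::fabs(V) > 200.0) { aborted = true; break; }

    if (!above && V > v_thr && (t - last_spike) > refrac) {
      spikes.push_back(t);
      last_spike = t;
      above = true;
    } else if (above && V < v_thr - 10.0) {
      above = false;
    }
  }

  return List::create(
    _["spike_times_ms"] = wrap(spikes),
    _["t_ms"] = rec_t[Range(0, std::max(ir - 1, 0))],
    _["v"] = rec_v[Range(0, std::max(ir - 1, 0))],
    _["ca_md"] = rec_camd[Range(0, std::max(ir - 1, 0))],
    _["ca_bulk"] = rec_cab[Range(0, std::max(ir - 1, 0))],
    _["open_sk"] = rec_sk[Range(0, std::max(ir - 1, 0))],
    _["open_trpv4"] = rec_v4[Range(0, std::max(ir - 1, 0))],
    _["open_trpm2"] = rec_m2[Range(0, std::max(ir - 1, 0))],
    _["aborted"] = aborted);
}
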