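// Microscopic QIF E-I network: Euler stepping with threshold/reset,
// refractory hold, and first-order synaptic filtering driven by population
// spike counts (delta-rate increments applied one step after each spike).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_qif_simulate(NumericVector eta_e, NumericVector eta_i,
                      NumericVector V0e, NumericVector V0i,
                      List pars, List forcing, SEXP sched,
                      double t0, double t_end, double dt,
                      double V_th, double V_reset,
                      double record_dt) {
  double tau_e = as<double>(pars["tau_e"]);
  double tau_i = as<double>(pars["tau_i"]);
  double tau_se = as<double>(pars["tau_se"]);
  double tau_si = as<double>(pars["tau_si"]);
  double J_ee = as<double>(pars["J_ee"]);
  double J_ei = as<double>(pars["J_ei"]);
  double J_ie = as<double>(pars["J_ie"]);
  double J_ii = as<double>(pars["J_ii"]);
  double Ie_bar0 = as<double>(pars["Ie_ext_bar"]);
  double Ii_bar0 = as<double>(pars["Ii_ext_bar"]);

  int Ne = eta_e.size(), Ni = eta_i.size();

  // forcing (von Mises inputs + optional square pulse on the E population)
  bool to_e = as<bool>(forcing["to_e"]);
  bool to_i = as<bool>(forcing["to_i"]);
  double t_on = as<double>(forcing["t_on"]);
  List ins = forcing["inputs"];
  int nin = ins.size();
  std::vector<double> inA(nin), inT(nin), inK(nin), inMu(nin), inI0e(nin);
  for (int k = 0; k < nin; ++k) {
    List in = ins[k];
    inA[k] = as<double>(in["A"]);
    inT[k] = as<double>(in["T"]);
    inK[k] = as<double>(in["kappa"]);
    inMu[k] = as<double>(in["mu"]);
    inI0e[k] = R::bessel_i(inK[k], 0.0, 2.0);
  }
  bool has_pulse = forcing.containsElementNamed("pulse") &&
                   !Rf_isNull(forcing["pulse"]);
  double p_amp = 0, p_dur = 0, p_onset = 0;
  if (has_pulse) {
    List pu = forcing["pulse"];
    p_amp = as<double>(pu["amplitude"]);
    p_dur = as<double>(pu["duration"]);
    p_onset = as<double>(pu["onset"]);
  }

  // drive schedule (rows: t, Ie, Ii)
  std::vector<double> st, sIe, sIi;
  if (!Rf_isNull(sched)) {
    NumericMatrix m(sched);
    for (int k = 0; k < m.nrow(); ++k) {
      st.push_back(m(k, 0)); sIe.push_back(m(k, 1)); sIi.push_back(m(k, 2));
    }
  }

  double Tref_e = 2.0 * tau_e / V_th, Tref_i = 2.0 * tau_i / V_th;
  int refr_steps_e = (int)std::lround(Tref_e / dt);
  int refr_steps_i = (int)std::lround(Tref_i / dt);

  std::vector<double> Ve(V0e.begin(), V0e.end()), Vi(V0i.begin(), V0i.end());
  std::vector<int> ref_e(Ne, 0), ref_i(Ni, 0);
  double See = 0, Sei = 0, Sie = 0, Sii = 0;
  int ne_prev = 0, ni_prev = 0;  // spikes in the previous step

  std::vector<double> sp_te, sp_ti;
  std::vector<int> sp_ie, sp_ii;
  sp_te.reserve(1 << 16); sp_ie.reserve(1 << 16);
  sp_ti.reserve(1 << 16); sp_ii.reserve(1 << 16);

  bool record = record_dt > 0;
  int rec_every = record ? std::max(1, (int)std::lround(record_dt / dt)) : 0;
  std::vector<double> rec_t, rec_See, rec_Sei, rec_Sie, rec_Sii;

  long nsteps = (long)std::llround((t_end - t0) / dt);
  double t = t0;
  for (long s = 0; s < nsteps; ++s) {
    t = t0 + s * dt;
    // synaptic update uses spike counts from the previous step
    See += dt * (-See) / tau_se + J_ee * ne_prev / ((double)Ne * tau_se);
    Sei += dt * (-Sei) / tau_si + J_ei * ni_prev / ((double)Ni * tau_si);
    Sie += dt * (-Sie) / tau_se + J_ie * ne_prev / ((double)Ne * tau_se);
    Sii += dt * (-Sii) / tau_si + J_ii * ni_prev / ((double)Ni * tau_si);

    double Ie_bar = Ie_bar0, Ii_bar = Ii_bar0;
    for (size_t k = 0; k < st.size(); ++k) {
      if (t >= st[k]) { Ie_bar = sIe[k]; Ii_bar = sIi[k]; } else break;
    }
    double g = 0.0;
    if (t >= t_on) {
      for (int k = 0; k < nin; ++k) {
        double c = std::cos(2.0 * M_PI * (t - inMu[k]) / inT[k]);
        g += inA[k] * std::exp(inK[k] * (c - 1.0)) / inI0e[k];
      }
    }
    double pv = 0.0;
    if (has_pulse && t >= p_onset && t < p_onset + p_dur) pv = p_amp;

    double I_e = Ie_bar + tau_e * ((to_e ? g : 0.0) + pv)
                 + tau_e * See - tau_e * Sei;
    double I_i = Ii_bar + tau_i * (to_i ? g : 0.0)
                 + tau_i * Sie - tau_i * Sii;

    int ne_now = 0, ni_now = 0;
    for (int j = 0; j < Ne; ++j) {
      if (ref_e[j] > 0) { --ref_e[j]; continue; }
      double V = Ve[j];
      V += dt * (V * V + eta_e[j] + I_e) / tau_e;
      if (V >= V_th) {
        sp_te.push_back(t + dt);
        sp_ie.push_back(j + 1);
        ++ne_now;
        V = V_reset;
        ref_e[j] = refr_steps_e;
      }
      Ve[j] = V;
    }
    for (int j = 0; j < Ni; ++j) {
      if (ref_i[j] > 0) { --ref_i[j]; continue; }
      double V = Vi[j];
      V += dt * (V * V + eta_i[j] + I_i) / tau_i;
      if (V >= V_th) {
        sp_ti.push_back(t + dt);
        sp_ii.push_back(j + 1);
        ++ni_now;
        V = V_reset;
        ref_i[j] = refr_steps_i;
      }
      Vi[j] = V;
    }
    if (!std::isfinite(Ve[0]) || !std::isfinite(Vi[0]))
      stop("non-finite voltage in QIF simulation");
    ne_prev = ne_now;
    ni_prev = ni_now;

    if (record && (s % rec_every == 0)) {
      rec_t.push_back(t);
      rec_See.push_back(See); rec_Sei.push_back(Sei);
      rec_Sie.push_back(Sie); rec_Sii.push_back(Sii);
    }
  }

  List syn = R_NilValue;
  if (record) {
    syn = DataFrame::create(_["t"] = rec_t, _["S_ee"] = rec_See,
                            _["S_ei"] = rec_Sei, _["S_ie"] = rec_Sie,
                            _["S_ii"] = rec_Sii);
  }
  return List::create(
      _["spike_t_e"] = NumericVector(sp_te.begin(), sp_te.end()),
      _["spike_id_e"] = IntegerVector(sp_ie.begin(), sp_ie.end()),
      _["spike_t_i"] = NumericVector(sp_ti.begin(), sp_ti.end()),
      _["spike_id_i"] = IntegerVector(sp_ii.begin(), sp_ii.end()),
      _["synaptic"] = syn);
}
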