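// Core numerics for the exact E-I mean-field model and its phase reduction:
// Dormand-Prince 5(4) integration with dense output, V_e-maximum event
// detection, 8x8 variational flow, backward-time adjoint (iPRC) solver and
// the scalar phase equation with strobe recording.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>

using namespace Rcpp;

// positive modulus into [0, p)
static inline double pmod(double x, double p) {
  double m = x - std::floor(x / p) * p;
  if (m >= p) m -= p;
  return m;
}

// ---------------------------------------------------------------- parameters

struct MFParams {
  double tau_e, tau_i, delta_e, delta_i, eta_e, eta_i,
         tau_se, tau_si, J_ee, J_ei, J_ie, J_ii,
         Ie_bar, Ii_bar;
};

static MFParams as_mfparams(const List& p) {
  MFParams q;
  q.tau_e   = as<double>(p["tau_e"]);
  q.tau_i   = as<double>(p["tau_i"]);
  q.delta_e = as<double>(p["delta_e"]);
  q.delta_i = as<double>(p["delta_i"]);
  q.eta_e   = as<double>(p["eta_e"]);
  q.eta_i   = as<double>(p["eta_i"]);
  q.tau_se  = as<double>(p["tau_se"]);
  q.tau_si  = as<double>(p["tau_si"]);
  q.J_ee    = as<double>(p["J_ee"]);
  q.J_ei    = as<double>(p["J_ei"]);
  q.J_ie    = as<double>(p["J_ie"]);
  q.J_ii    = as<double>(p["J_ii"]);
  q.Ie_bar  = as<double>(p["Ie_ext_bar"]);
  q.Ii_bar  = as<double>(p["Ii_ext_bar"]);
  return q;
}

// ------------------------------------------------------------------- forcing

struct VMInput { double A, T, kappa, mu, i0e; };

struct SqPulse { double amp, dur, onset; bool on; };

// Step schedule for the tonic drives (protocol runs); empty = use baseline.
struct DriveSched {
  std::vector<double> t, Ie, Ii;
  void at(double tt, const MFParams& p, double& Ie_bar, double& Ii_bar) const {
    Ie_bar = p.Ie_bar; Ii_bar = p.Ii_bar;
    for (size_t k = 0; k < t.size(); ++k) {
      if (tt >= t[k]) { Ie_bar = Ie[k]; Ii_bar = Ii[k]; } else break;
    }
  }
};

struct Forcing {
  std::vector<VMInput> inputs;
  SqPulse pulse;
  bool to_e, to_i;
  double t_on;

  double g(double t) const {
    if (t < t_on) return 0.0;
    double s = 0.0;
    for (size_t k = 0; k < inputs.size(); ++k) {
      const VMInput& in = inputs[k];
      double c = std::cos(2.0 * M_PI * (t - in.mu) / in.T);
      s += in.A * std::exp(in.kappa * (c - 1.0)) / in.i0e;
    }
    return s;
  }
  double pulse_val(double t) const {
    if (!pulse.on) return 0.0;
    return (t >= pulse.onset && t < pulse.onset + pulse.dur) ? pulse.amp : 0.0;
  }
};

static Forcing as_forcing(const List& f) {
  Forcing F;
  F.to_e = as<bool>(f["to_e"]);
  F.to_i = as<bool>(f["to_i"]);
  F.t_on = as<double>(f["t_on"]);
  List ins = f["inputs"];
  for (int k = 0; k < ins.size(); ++k) {
    List in = ins[k];
    VMInput v;
    v.A = as<double>(in["A"]);
    v.T = as<double>(in["T"]);
    v.kappa = as<double>(in["kappa"]);
    v.mu = as<double>(in["mu"]);
    // exponentially scaled modified Bessel I0: exp(-kappa) * I0(kappa)
    v.i0e = R::bessel_i(v.kappa, 0.0, 2.0);
    F.inputs.push_back(v);
  }
  F.pulse.on = false;
  F.pulse.amp = F.pulse.dur = F.pulse.onset = 0.0;
  if (f.containsElementNamed("pulse") && !Rf_isNull(f["pulse"])) {
    List pu = f["pulse"];
    F.pulse.on = true;
    F.pulse.amp = as<double>(pu["amplitude"]);
    F.pulse.dur = as<double>(pu["duration"]);
    F.pulse.onset = as<double>(pu["onset"]);
  }
  return F;
}

static DriveSched as_sched(SEXP s) {
  DriveSched d;
  if (Rf_isNull(s)) return d;
  NumericMatrix m(s);
  for (int k = 0; k < m.nrow(); ++k) {
    d.t.push_back(m(k, 0)); d.Ie.push_back(m(k, 1)); d.Ii.push_back(m(k, 2));
  }
  return d;
}


// step cap resolving the narrowest periodic volley (avoids stepping over
// sharply peaked high-coherence inputs)
static double forcing_hmax(const Forcing& F) {
  double hm = 0.0;
  for (size_t k = 0; k < F.inputs.size(); ++k) {
    double w = F.inputs[k].T / 8.0;
    if (hm == 0.0 || w < hm) hm = w;
  }
  return hm;
}

// ------------------------------------------------------------ mean-field RHS

static inline void mf_rhs(double t, const double* y, double* dy,
                          const MFParams& p, const Forcing& F,
                          const DriveSched& S) {
  double Ie_bar, Ii_bar;
  S.at(t, p, Ie_bar, Ii_bar);
  double g = F.g(t);
  double pv = F.pulse_val(t);
  double re = y[0], Ve = y[1], See = y[2], Sei = y[3];
  double ri = y[4], Vi = y[5], Sie = y[6], Sii = y[7];
  double ge = F.to_e ? g : 0.0;
  double gi = F.to_i ? g : 0.0;
  dy[0] = p.delta_e / (M_PI * p.tau_e * p.tau_e) + 2.0 * re * Ve / p.tau_e;
  double pre = p.tau_e * M_PI * re;
  dy[1] = (Ve * Ve + p.eta_e + Ie_bar - pre * pre) / p.tau_e
          + See - Sei + ge + pv;
  dy[2] = (-See + p.J_ee * re) / p.tau_se;
  dy[3] = (-Sei + p.J_ei * ri) / p.tau_si;
  dy[4] = p.delta_i / (M_PI * p.tau_i * p.tau_i) + 2.0 * ri * Vi / p.tau_i;
  double pri = p.tau_i * M_PI * ri;
  dy[5] = (Vi * Vi + p.eta_i + Ii_bar - pri * pri) / p.tau_i
          + Sie - Sii + gi;
  dy[6] = (-Sie + p.J_ie * re) / p.tau_se;
  dy[7] = (-Sii + p.J_ii * ri) / p.tau_si;
}

// Analytic Jacobian of the autonomous part (forcing is state-independent).
static void mf_jac(const double* y, double J[8][8], const MFParams& p) {
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 8; ++j) J[i][j] = 0.0;
  double re = y[0], Ve = y[1], ri = y[4], Vi = y[5];
  J[0][0] = 2.0 * Ve / p.tau_e;
  J[0][1] = 2.0 * re / p.tau_e;
  J[1][0] = -2.0 * p.tau_e * M_PI * M_PI * re;
  J[1][1] = 2.0 * Ve / p.tau_e;
  J[1][2] = 1.0;
  J[1][3] = -1.0;
  J[2][0] = p.J_ee / p.tau_se;
  J[2][2] = -1.0 / p.tau_se;
  J[3][4] = p.J_ei / p.tau_si;
  J[3][3] = -1.0 / p.tau_si;
  J[4][4] = 2.0 * Vi / p.tau_i;
  J[4][5] = 2.0 * ri / p.tau_i;
  J[5][4] = -2.0 * p.tau_i * M_PI * M_PI * ri;
  J[5][5] = 2.0 * Vi / p.tau_i;
  J[5][6] = 1.0;
  J[5][7] = -1.0;
  J[6][0] = p.J_ie / p.tau_se;
  J[6][6] = -1.0 / p.tau_se;
  J[7][4] = p.J_ii / p.tau_si;
  J[7][7] = -1.0 / p.tau_si;
}

// --------------------------------------------------- Dormand-Prince stepper

typedef std::function<void(double, const double*, double*)> RhsFun;

struct DenseStep {
  double t0, h;
  int n;
  std::vector<double> r1, r2, r3, r4, r5;
  void eval(double t, double* out) const {
    double th = (t - t0) / h;
    double th1 = 1.0 - th;
    for (int i = 0; i < n; ++i)
      out[i] = r1[i] + th * (r2[i] + th1 * (r3[i] + th * (r4[i] + th1 * r5[i])));
  }
};

typedef std::function<void(double, double, const DenseStep&)> StepObs;

// DOPRI5(4) with FSAL and 4th-order continuous output (Hairer et al.).
static void dopri5(const RhsFun& f, int n, double t0, double t1,
                   std::vector<double>& y, double tol, const StepObs& obs,
                   double hmax = 0.0, bool abs_scale = false) {
  // abs_scale: pure absolute error control; needed for the phase lift,
  // whose magnitude grows without bound while only its value mod T* matters
  if (t1 <= t0) return;
  static const double
    c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9,
    a21 = 1.0/5,
    a31 = 3.0/40, a32 = 9.0/40,
    a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9,
    a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
    a54 = -212.0/729,
    a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
    a64 = 49.0/176, a65 = -5103.0/18656,
    a71 = 35.0/384, a73 = 500.0/1113, a74 = 125.0/192,
    a75 = -2187.0/6784, a76 = 11.0/84,
    e1 = 71.0/57600, e3 = -71.0/16695, e4 = 71.0/1920,
    e5 = -17253.0/339200, e6 = 22.0/525, e7 = -1.0/40,
    d1 = -12715105075.0/11282082432.0, d3 = 87487479700.0/32700410799.0,
    d4 = -10690763975.0/1880347072.0, d5 = 701980252875.0/199316789632.0,
    d6 = -1453857185.0/822651844.0, d7 = 69997945.0/29380423.0;

  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), y1(n);
  DenseStep D;
  D.n = n;
  D.r1.resize(n); D.r2.resize(n); D.r3.resize(n); D.r4.resize(n);
  D.r5.resize(n);

  double t = t0;
  double h = std::min(1e-2, t1 - t0);
  if (hmax > 0.0) h = std::min(h, hmax);
  f(t, y.data(), k1.data());
  long nstep = 0;
  const long maxstep = 100000000L;
  while (t < t1) {
    if (++nstep > maxstep) stop("dopri5: maximum step count exceeded");
    if (h < 1e-13 * std::max(1.0, std::fabs(t)))
      stop("dopri5: step size underflow (possible blow-up)");
    bool last = false;
    if (t + h >= t1) { h = t1 - t; last = true; }

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    f(t + c2 * h, ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    f(t + c3 * h, ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    f(t + c4 * h, ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i]
                            + a54 * k4[i]);
    f(t + c5 * h, ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i]
                            + a64 * k4[i] + a65 * k5[i]);
    f(t + h, ytmp.data(), k6.data());
    for (int i = 0; i < n; ++i)
      y1[i] = y[i] + h * (a71 * k1[i] + a73 * k3[i] + a74 * k4[i]
                          + a75 * k5[i] + a76 * k6[i]);
    f(t + h, y1.data(), k7.data());

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i]
                       + e6 * k6[i] + e7 * k7[i]);
      double sc = abs_scale ? tol
        : tol + tol * std::max(std::fabs(y[i]), std::fabs(y1[i]));
      double q = ei / sc;
      err += q * q;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) {
      h *= 0.25;
      continue;
    }
    if (err <= 1.0) {
      // accept; build dense coefficients
      for (int i = 0; i < n; ++i) {
        double dy = y1[i] - y[i];
        double bspl = h * k1[i] - dy;
        D.r1[i] = y[i];
        D.r2[i] = dy;
        D.r3[i] = bspl;
        D.r4[i] = dy - h * k7[i] - bspl;
        D.r5[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i]
                       + d6 * k6[i] + d7 * k7[i]);
      }
      D.t0 = t; D.h = h;
      double tnew = t + h;
      if (obs) obs(t, tnew, D);
      t = tnew;
      std::swap(y, y1);
      std::swap(k1, k7);  // FSAL
      if (!last) {
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        h *= std::min(5.0, std::max(0.2, fac));
        if (hmax > 0.0) h = std::min(h, hmax);
      }
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      h *= std::max(0.2, fac);
    }
  }
}

// Integration breakpoints where the vector field is non-smooth in t.
static std::vector<double> breakpoints(double t0, double t1, const Forcing& F,
                                       const DriveSched& S) {
  std::vector<double> b;
  b.push_back(t0);
  if (std::isfinite(F.t_on) && F.t_on > t0 && F.t_on < t1)
    b.push_back(F.t_on);
  if (F.pulse.on) {
    if (F.pulse.onset > t0 && F.pulse.onset < t1) b.push_back(F.pulse.onset);
    double off = F.pulse.onset + F.pulse.dur;
    if (off > t0 && off < t1) b.push_back(off);
  }
  for (size_t k = 0; k < S.t.size(); ++k)
    if (S.t[k] > t0 && S.t[k] < t1) b.push_back(S.t[k]);
  b.push_back(t1);
  std::sort(b.begin(), b.end());
  b.erase(std::unique(b.begin(), b.end()), b.end());
  return b;
}

static void check_finite(const std::vector<double>& y) {
  for (size_t i = 0; i < y.size(); ++i)
    if (!std::isfinite(y[i]))
      stop("non-finite state encountered (trajectory blow-up)");
}

// ------------------------------------------------------- exported: integrate

// [[Rcpp::export]]
NumericMatrix cpp_mf_integrate(NumericVector y0, NumericVector times,
                               List pars, List forcing, SEXP sched,
                               double tol) {
  MFParams P = as_mfparams(pars);
  Forcing F = as_forcing(forcing);
  DriveSched S = as_sched(sched);
  int nt = times.size();
  NumericMatrix out(nt, 8);
  std::vector<double> y(y0.begin(), y0.end());
  for (int j = 0; j < 8; ++j) out(0, j) = y[j];
  if (nt == 1) return out;

  RhsFun f = [&](double t, const double* yy, double* dy) {
    mf_rhs(t, yy, dy, P, F, S);
  };
  int next = 1;
  std::vector<double> tmp(8);
  StepObs obs = [&](double ta, double tb, const DenseStep& D) {
    while (next < nt && times[next] <= tb + 1e-14) {
      D.eval(times[next], tmp.data());
      for (int j = 0; j < 8; ++j) out(next, j) = tmp[j];
      ++next;
    }
  };
  std::vector<double> bp = breakpoints(times[0], times[nt - 1], F, S);
  double hm = forcing_hmax(F);
  for (size_t k = 0; k + 1 < bp.size(); ++k)
    dopri5(f, 8, bp[k], bp[k + 1], y, tol, obs, hm);
  check_finite(y);
  // fill any trailing times (== t1) with final state
  for (; next < nt; ++next)
    for (int j = 0; j < 8; ++j) out(next, j) = y[j];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mf_rhs(NumericVector y, double t, List pars, List forcing,
                         SEXP sched) {
  MFParams P = as_mfparams(pars);
  Forcing F = as_forcing(forcing);
  DriveSched S = as_sched(sched);
  NumericVector dy(8);
  mf_rhs(t, y.begin(), dy.begin(), P, F, S);
  return dy;
}

// [[Rcpp::export]]
NumericMatrix cpp_mf_jac(NumericVector y, List pars) {
  MFParams P = as_mfparams(pars);
  double J[8][8];
  mf_jac(y.begin(), J, P);
  NumericMatrix out(8, 8);
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 8; ++j) out(i, j) = J[i][j];
  return out;
}

// ------------------------------------------- exported: V_e maximum detection

// [[Rcpp::export]]
List cpp_mf_events(NumericVector y0, double t0, double t1, List pars,
                   List forcing, SEXP sched, double tol) {
  MFParams P = as_mfparams(pars);
  Forcing F = as_forcing(forcing);
  DriveSched S = as_sched(sched);
  RhsFun f = [&](double t, const double* yy, double* dy) {
    mf_rhs(t, yy, dy, P, F, S);
  };
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> ev_t;
  std::vector<std::vector<double> > ev_y;
  std::vector<double> st(8), dst(8);

  StepObs obs = [&](double ta, double tb, const DenseStep& D) {
    // event function: dVe/dt, + -> - crossing marks a Ve maximum
    D.eval(ta, st.data());
    f(ta, st.data(), dst.data());
    double ga = dst[1];
    D.eval(tb, st.data());
    f(tb, st.data(), dst.data());
    double gb = dst[1];
    if (ga > 0.0 && gb <= 0.0) {
      double lo = ta, hi = tb;
      for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (lo + hi);
        D.eval(mid, st.data());
        f(mid, st.data(), dst.data());
        if (dst[1] > 0.0) lo = mid; else hi = mid;
        if (hi - lo < 1e-13 * std::max(1.0, std::fabs(hi))) break;
      }
      double te = 0.5 * (lo + hi);
      D.eval(te, st.data());
      ev_t.push_back(te);
      ev_y.push_back(st);
    }
  };
  std::vector<double> bp = breakpoints(t0, t1, F, S);
  double hm = forcing_hmax(F);
  for (size_t k = 0; k + 1 < bp.size(); ++k)
    dopri5(f, 8, bp[k], bp[k + 1], y, tol, obs, hm);
  check_finite(y);

  int ne = ev_t.size();
  NumericMatrix em(ne, 8);
  NumericVector et(ne);
  for (int k = 0; k < ne; ++k) {
    et[k] = ev_t[k];
    for (int j = 0; j < 8; ++j) em(k, j) = ev_y[k][j];
  }
  return List::create(_["times"] = et, _["states"] = em,
                      _["y_end"] = NumericVector(y.begin(), y.end()));
}

// -------------------------------------------- exported: flow with variational

// [[Rcpp::export]]
List cpp_mf_flow(NumericVector y0, double t0, double t1, List pars,
                 List forcing, SEXP sched, double tol, bool with_var) {
  MFParams P = as_mfparams(pars);
  Forcing F = as_forcing(forcing);
  DriveSched S = as_sched(sched);

  if (!with_var) {
    std::vector<double> y(y0.begin(), y0.end());
    RhsFun f = [&](double t, const double* yy, double* dy) {
      mf_rhs(t, yy, dy, P, F, S);
    };
    std::vector<double> bp = breakpoints(t0, t1, F, S);
    double hm = forcing_hmax(F);
    for (size_t k = 0; k + 1 < bp.size(); ++k)
      dopri5(f, 8, bp[k], bp[k + 1], y, tol, StepObs(), hm);
    check_finite(y);
    return List::create(_["y"] = NumericVector(y.begin(), y.end()));
  }

  // state + variational: y[0..7], M column-major in y[8..71], dM/dt = J M
  std::vector<double> y(72, 0.0);
  for (int i = 0; i < 8; ++i) y[i] = y0[i];
  for (int i = 0; i < 8; ++i) y[8 + i * 8 + i] = 1.0;
  RhsFun f = [&](double t, const double* yy, double* dy) {
    mf_rhs(t, yy, dy, P, F, S);
    double J[8][8];
    mf_jac(yy, J, P);
    for (int col = 0; col < 8; ++col) {
      const double* m = yy + 8 + col * 8;
      double* dm = dy + 8 + col * 8;
      for (int i = 0; i < 8; ++i) {
        double s = 0.0;
        for (int j = 0; j < 8; ++j) s += J[i][j] * m[j];
        dm[i] = s;
      }
    }
  };
  std::vector<double> bp = breakpoints(t0, t1, F, S);
  double hm = forcing_hmax(F);
  for (size_t k = 0; k + 1 < bp.size(); ++k)
    dopri5(f, 72, bp[k], bp[k + 1], y, tol, StepObs(), hm);
  check_finite(y);
  NumericVector yend(8);
  NumericMatrix M(8, 8);
  for (int i = 0; i < 8; ++i) yend[i] = y[i];
  for (int col = 0; col < 8; ++col)
    for (int i = 0; i < 8; ++i) M(i, col) = y[8 + col * 8 + i];
  return List::create(_["y"] = yend, _["M"] = M);
}

// ------------------------------------------------ periodic cubic Hermite grid

struct HermiteGrid {
  int n;
  double period, h;
  const double* val;  // n x m, column-major (R matrix)
  const double* der;
  int m;
  void eval(double t, double* out) const {
    double s = pmod(t, period);
    int j = (int)std::floor(s / h);
    if (j >= n) j = n - 1;
    int j1 = (j + 1) % n;
    double u = (s - j * h) / h;
    double u2 = u * u, u3 = u2 * u;
    double h00 = 2 * u3 - 3 * u2 + 1, h10 = u3 - 2 * u2 + u,
           h01 = -2 * u3 + 3 * u2, h11 = u3 - u2;
    for (int c = 0; c < m; ++c) {
      double y0 = val[c * n + j], y1 = val[c * n + j1];
      double d0 = der[c * n + j], d1 = der[c * n + j1];
      out[c] = h00 * y0 + h10 * h * d0 + h01 * y1 + h11 * h * d1;
    }
  }
};

// ------------------------------------------------------- exported: adjoint

// Backward-time integration of dZ/dt = -M^T(gamma(t)) Z until the periodic
// solution is reached; cycle supplied as uniform samples with derivatives.
// [[Rcpp::export]]
List cpp_adjoint(NumericMatrix cyc_y, NumericMatrix cyc_f, double Tstar,
                 List pars, double tol, int max_periods, double conv_tol) {
  MFParams P = as_mfparams(pars);
  int n = cyc_y.nrow();
  HermiteGrid G;
  G.n = n; G.period = Tstar; G.h = Tstar / n;
  G.val = cyc_y.begin(); G.der = cyc_f.begin(); G.m = 8;

  // gamma'(0) for normalization along the neutral direction
  std::vector<double> f0(8);
  for (int j = 0; j < 8; ++j) f0[j] = cyc_f(0, j);

  // integrate in sigma (= -t): dZ/dsigma = +M^T(gamma(-sigma)) Z
  std::vector<double> gam(8);
  RhsFun f = [&](double sg, const double* z, double* dz) {
    G.eval(-sg, gam.data());
    double J[8][8];
    mf_jac(gam.data(), J, P);
    for (int i = 0; i < 8; ++i) {
      double s = 0.0;
      for (int j = 0; j < 8; ++j) s += J[j][i] * z[j];  // M^T z
      dz[i] = s;
    }
  };

  std::vector<double> Z(8, 0.0);
  Z[1] = 1.0;  // arbitrary start with a V_e component
  std::vector<double> Zprev(8, 0.0);
  int used = 0;
  double delta = NA_REAL;
  bool converged = false;
  for (int k = 0; k < max_periods; ++k) {
    dopri5(f, 8, k * Tstar, (k + 1) * Tstar, Z, tol, StepObs());
    double c = 0.0;
    for (int j = 0; j < 8; ++j) c += Z[j] * f0[j];
    if (std::fabs(c) < 1e-300) stop("adjoint iteration degenerated");
    for (int j = 0; j < 8; ++j) Z[j] /= c;
    double d = 0.0, zmax = 0.0;
    for (int j = 0; j < 8; ++j) {
      d = std::max(d, std::fabs(Z[j] - Zprev[j]));
      zmax = std::max(zmax, std::fabs(Z[j]));
    }
    Zprev = Z;
    used = k + 1;
    delta = d / std::max(zmax, 1e-12);
    if (k > 0 && delta < conv_tol) { converged = true; break; }
  }

  // one more period, recording Z at the cycle grid times
  // sigma = used*Tstar + s, physical time -s - used*Tstar ~ mod = Tstar - s
  NumericMatrix Zg(n, 8);
  for (int j = 0; j < 8; ++j) Zg(0, j) = Z[j];
  double s0 = used * Tstar;
  // record targets: grid time t_j = j*h  ->  sigma = s0 + (Tstar - t_j)
  std::vector<double> rec(n - 1);
  for (int j = 1; j < n; ++j) rec[n - 1 - j] = s0 + (Tstar - j * G.h);
  size_t next = 0;
  std::vector<double> tmp(8);
  StepObs obs = [&](double ta, double tb, const DenseStep& D) {
    while (next < rec.size() && rec[next] <= tb + 1e-12) {
      D.eval(rec[next], tmp.data());
      int j = n - 1 - (int)next;  // grid index
      for (int c = 0; c < 8; ++c) Zg(j, c) = tmp[c];
      ++next;
    }
  };
  dopri5(f, 8, s0, s0 + Tstar, Z, tol, obs);

  return List::create(_["Z"] = Zg, _["periods"] = used,
                      _["delta"] = delta, _["converged"] = converged);
}

// --------------------------------------------------- exported: phase equation

struct ZeiPack {
  HermiteGrid zg;    // Zei (values + first derivative as slopes)
  HermiteGrid dzg;   // Zei' (values + second derivative as slopes)
  double Tstar;
};

static ZeiPack as_zpack(const List& zp) {
  ZeiPack z;
  z.Tstar = as<double>(zp["Tstar"]);
  NumericVector v = zp["z"], dv = zp["zd"], d2v = zp["zd2"];
  int n = v.size();
  z.zg.n = n; z.zg.period = z.Tstar; z.zg.h = z.Tstar / n;
  z.zg.val = v.begin(); z.zg.der = dv.begin(); z.zg.m = 1;
  z.dzg.n = n; z.dzg.period = z.Tstar; z.dzg.h = z.Tstar / n;
  z.dzg.val = dv.begin(); z.dzg.der = d2v.begin(); z.dzg.m = 1;
  return z;
}

// NOTE: the R wrappers keep zp alive during the call, so holding raw
// pointers into its vectors is safe.

// [[Rcpp::export]]
List cpp_phase_flow(double theta0, double t0, double t1,
                    NumericVector rec_times, List zpack, List forcing,
                    double tol, bool with_var) {
  ZeiPack Z = as_zpack(zpack);
  Forcing F = as_forcing(forcing);
  int n = with_var ? 2 : 1;
  std::vector<double> y(n);
  y[0] = theta0;
  if (with_var) y[1] = 1.0;

  RhsFun f = [&](double t, const double* yy, double* dy) {
    double g = F.g(t);
    double z;
    Z.zg.eval(yy[0], &z);
    dy[0] = 1.0 + g * z;
    if (n == 2) {
      double dz;
      Z.dzg.eval(yy[0], &dz);
      dy[1] = g * dz * yy[1];
    }
  };

  int nr = rec_times.size();
  NumericVector rth(nr), rv(nr);
  int next = 0;
  std::vector<double> tmp(n);
  StepObs obs = [&](double ta, double tb, const DenseStep& D) {
    while (next < nr && rec_times[next] <= tb + 1e-12) {
      D.eval(rec_times[next], tmp.data());
      rth[next] = tmp[0];
      rv[next] = (n == 2) ? tmp[1] : NA_REAL;
      ++next;
    }
  };
  // record t0 if requested
  while (next < nr && rec_times[next] <= t0) {
    rth[next] = theta0; rv[next] = with_var ? 1.0 : NA_REAL; ++next;
  }
  std::vector<double> bp = breakpoints(t0, t1, F, DriveSched());
  double hm = forcing_hmax(F);
  for (size_t k = 0; k + 1 < bp.size(); ++k)
    dopri5(f, n, bp[k], bp[k + 1], y, tol, obs, hm, true);
  for (; next < nr; ++next) {
    rth[next] = y[0];
    rv[next] = (n == 2) ? y[1] : NA_REAL;
  }
  return List::create(_["theta"] = rth, _["v"] = rv,
                      _["theta_end"] = y[0],
                      _["v_end"] = with_var ? y[1] : NA_REAL);
}
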