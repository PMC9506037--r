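// Fast evaluation core for the CPA equation of state.
//
// The R level owns the user-facing API and a pure-R reference
// implementation of every quantity computed here; the two routes are
// compared in the test suite.  Units throughout: T in K, P in bar,
// V in L/mol, energies in bar.L/mol, R = 0.083145 bar.L/(mol.K).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double RGAS = 0.083145;

struct MixData {
  int nc, ns;
  std::vector<double> a0, b, c1, tc;
  std::vector<double> kij;            // nc x nc, column-major
  std::vector<int> site_comp;         // 0-based component owning each site class
  std::vector<double> site_mult;
  std::vector<double> eps, beta, bij; // ns x ns site-pair tables
  double kij_at(int i, int j) const { return kij[i + nc * j]; }
};

static MixData unpack(const List& mix) {
  MixData m;
  m.nc = as<int>(mix["nc"]);
  m.ns = as<int>(mix["ns"]);
  m.a0 = as<std::vector<double>>(mix["a0"]);
  m.b  = as<std::vector<double>>(mix["b"]);
  m.c1 = as<std::vector<double>>(mix["c1"]);
  m.tc = as<std::vector<double>>(mix["tc"]);
  m.kij = as<std::vector<double>>(mix["kij"]);
  if (m.ns > 0) {
    m.site_comp = as<std::vector<int>>(mix["site_comp"]); // 1-based from R
    for (int s = 0; s < m.ns; ++s) m.site_comp[s] -= 1;
    m.site_mult = as<std::vector<double>>(mix["site_mult"]);
    m.eps  = as<std::vector<double>>(mix["eps_mat"]);
    m.beta = as<std::vector<double>>(mix["beta_mat"]);
    m.bij  = as<std::vector<double>>(mix["bij_mat"]);
  }
  return m;
}

// Soave alpha-function attractive parameter, valid above tc as well.
static inline double soave_a(double a0, double c1, double tc, double T) {
  double t = 1.0 + c1 * (1.0 - std::sqrt(T / tc));
  return a0 * t * t;
}

// Solve X = 1 / (1 + M X) for the unbonded-site fractions.
// Damped successive substitution, then Newton (Gauss elimination).
static void solve_sites(const std::vector<double>& M, int ns,
                        std::vector<double>& X) {
  if (ns == 0) return;
  std::vector<double> Xn(ns), F(ns), u(ns);
  const double tol = 1e-14;
  // successive substitution with damping 0.5
  for (int it = 0; it < 60; ++it) {
    double res = 0.0;
    for (int s = 0; s < ns; ++s) {
      double acc = 0.0;
      for (int t = 0; t < ns; ++t) acc += M[s + ns * t] * X[t];
      double Xi = 1.0 / (1.0 + acc);
      res = std::max(res, std::fabs(Xi - X[s]));
      Xn[s] = 0.5 * Xi + 0.5 * X[s];
    }
    X = Xn;
    if (res < tol) return;
  }
  // Newton fallback: F_s = X_s - 1/(1+(MX)_s)
  std::vector<double> J(ns * ns);
  for (int it = 0; it < 100; ++it) {
    double res = 0.0;
    for (int s = 0; s < ns; ++s) {
      double acc = 0.0;
      for (int t = 0; t < ns; ++t) acc += M[s + ns * t] * X[t];
      u[s] = 1.0 + acc;
      F[s] = X[s] - 1.0 / u[s];
      res = std::max(res, std::fabs(F[s]));
    }
    if (res < tol) return;
    for (int s = 0; s < ns; ++s)
      for (int t = 0; t < ns; ++t)
        J[s + ns * t] = (s == t ? 1.0 : 0.0) + M[s + ns * t] / (u[s] * u[s]);
    // Gaussian elimination with partial pivoting
    for (int k = 0; k < ns; ++k) {
      int p = k;
      for (int r = k + 1; r < ns; ++r)
        if (std::fabs(J[r + ns * k]) > std::fabs(J[p + ns * k])) p = r;
      if (p != k) {
        for (int c = 0; c < ns; ++c) std::swap(J[k + ns * c], J[p + ns * c]);
        std::swap(F[k], F[p]);
      }
      for (int r = k + 1; r < ns; ++r) {
        double f = J[r + ns * k] / J[k + ns * k];
        for (int c = k; c < ns; ++c) J[r + ns * c] -= f * J[k + ns * c];
        F[r] -= f * F[k];
      }
    }
    // back substitution; Newton step stored in F
    for (int k = ns - 1; k >= 0; --k) {
      double acc = F[k];
      for (int c = k + 1; c < ns; ++c) acc -= J[k + ns * c] * F[c];
      F[k] = acc / J[k + ns * k];
    }
    for (int s = 0; s < ns; ++s) {
      X[s] -= F[s];
      if (X[s] <= 0.0) X[s] = 1e-12;
      if (X[s] > 1.0) X[s] = 1.0;
    }
  }
}

struct StateEval {
  double P, ares, h, amix, bmix, eta, g;
  std::vector<double> X;
};

// Full CPA evaluation at (T, V, x).  X0 is a warm start (may be empty).
static StateEval eval_state(const MixData& m, double T, double V,
                            const std::vector<double>& x,
                            std::vector<double>& X0) {
  StateEval st;
  int nc = m.nc, ns = m.ns;
  std::vector<double> ai(nc);
  for (int i = 0; i < nc; ++i) ai[i] = soave_a(m.a0[i], m.c1[i], m.tc[i], T);
  double amix = 0.0, bmix = 0.0;
  for (int i = 0; i < nc; ++i) {
    bmix += x[i] * m.b[i];
    for (int j = 0; j < nc; ++j)
      amix += x[i] * x[j] * std::sqrt(ai[i] * ai[j]) * (1.0 - m.kij_at(i, j));
  }
  double rho = 1.0 / V;
  double eta = bmix * rho / 4.0;
  double g = 1.0 / (1.0 - 1.9 * eta);
  double h = 0.0, ares_assoc = 0.0;
  if (ns > 0) {
    std::vector<double> M(ns * ns);
    for (int s = 0; s < ns; ++s)
      for (int t = 0; t < ns; ++t) {
        double bet = m.beta[s + ns * t];
        double del = 0.0;
        if (bet > 0.0) {
          double ep = m.eps[s + ns * t];
          del = g * (std::exp(ep / (RGAS * T)) - 1.0) * m.bij[s + ns * t] * bet;
        }
        M[s + ns * t] = rho * x[m.site_comp[t]] * m.site_mult[t] * del;
      }
    if ((int)X0.size() != ns) X0.assign(ns, 1.0);
    solve_sites(M, ns, X0);
    for (int s = 0; s < ns; ++s) {
      double xm = x[m.site_comp[s]] * m.site_mult[s];
      h += xm * (1.0 - X0[s]);
      ares_assoc += xm * (std::log(X0[s]) - 0.5 * X0[s] + 0.5);
    }
    st.X = X0;
  }
  double rdlng = 1.9 * eta * g; // rho * d ln g / d rho
  st.P = RGAS * T / (V - bmix) - amix / (V * (V + bmix)) -
         0.5 * (RGAS * T / V) * (1.0 + rdlng) * h;
  st.ares = -std::log(1.0 - bmix * rho) -
            amix / (bmix * RGAS * T) * std::log(1.0 + bmix * rho) + ares_assoc;
  st.h = h; st.amix = amix; st.bmix = bmix; st.eta = eta; st.g = g;
  return st;
}

// [[Rcpp::export]]
List cpp_state(List mix, double T, double V, NumericVector x) {
  MixData m = unpack(mix);
  std::vector<double> xv(x.begin(), x.end()), X0;
  StateEval st = eval_state(m, T, V, xv, X0);
  return List::create(_["P"] = st.P, _["ares"] = st.ares, _["h"] = st.h,
                      _["amix"] = st.amix, _["bmix"] = st.bmix,
                      _["eta"] = st.eta, _["g"] = st.g,
                      _["X"] = wrap(st.X));
}

// Volume roots of P(T, V) = P by sign scan on a log-spaced grid plus
// Illinois refinement.  Returns all roots found (ascending).
static std::vector<double> volume_roots(const MixData& m, double T, double P,
                                        const std::vector<double>& x) {
  double bmix = 0.0;
  for (int i = 0; i < m.nc; ++i) bmix += x[i] * m.b[i];
  double Vlo = bmix * 1.001;
  double Vhi = std::max(1e3 * RGAS * T / P, 50.0 * bmix);
  const int NV = 120;
  std::vector<double> Vg(NV), fg(NV);
  std::vector<double> X0;
  double lo = std::log(Vlo), hi = std::log(Vhi);
  for (int k = 0; k < NV; ++k) {
    Vg[k] = std::exp(lo + (hi - lo) * k / (NV - 1.0));
    fg[k] = eval_state(m, T, Vg[k], x, X0).P - P;
  }
  std::vector<double> roots;
  for (int k = 0; k + 1 < NV; ++k) {
    if (fg[k] == 0.0) { roots.push_back(Vg[k]); continue; }
    if (fg[k] * fg[k + 1] < 0.0) {
      double a = Vg[k], b2 = Vg[k + 1], fa = fg[k], fb = fg[k + 1];
      int side = 0;
      for (int it = 0; it < 300; ++it) {
        double c = (fa * b2 - fb * a) / (fa - fb);
        double fc = eval_state(m, T, c, x, X0).P - P;
        if (std::fabs(fc) <= 1e-13 * std::fabs(P) || std::fabs(b2 - a) < 1e-14 * c) {
          a = b2 = c; fa = fb = fc; break;
        }
        if (fc * fb < 0.0) { a = b2; fa = fb; b2 = c; fb = fc; side = 0; }
        else { b2 = c; fb = fc; if (side == 1) fa *= 0.5; side = 1; }
      }
      roots.push_back(0.5 * (a + b2));
    }
  }
  return roots;
}

// Residual Gibbs energy / RT at (T, V) for root selection.
static double gibbs_res(const MixData& m, double T, double V, double P,
                        const std::vector<double>& x) {
  std::vector<double> X0;
  StateEval st = eval_state(m, T, V, x, X0);
  double Z = P * V / (RGAS * T);
  return st.ares + Z - 1.0 - std::log(Z);
}

// hint: 0 = min Gibbs, 1 = liquid (smallest), 2 = vapor (largest)
// [[Rcpp::export]]
List cpp_volume(List mix, double T, double P, NumericVector x, int hint) {
  MixData m = unpack(mix);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> roots = volume_roots(m, T, P, xv);
  if (roots.empty())
    return List::create(_["V"] = NA_REAL, _["roots"] = NumericVector(0),
                        _["nroots"] = 0);
  double V;
  if (roots.size() == 1) V = roots[0];
  else if (hint == 1) V = roots.front();
  else if (hint == 2) V = roots.back();
  else {
    double gl = gibbs_res(m, T, roots.front(), P, xv);
    double gv = gibbs_res(m, T, roots.back(), P, xv);
    // ties resolve to the vapor-like root
    V = (gl < gv - 1e-12) ? roots.front() : roots.back();
  }
  return List::create(_["V"] = V, _["roots"] = wrap(roots),
                      _["nroots"] = (int)roots.size());
}

// Analytic log fugacity coefficients at fixed (T, V, x); Z from the
// pressure computed at that volume.
static std::vector<double> lnphi_at_V(const MixData& m, double T, double V,
                                      const std::vector<double>& x,
                                      double& P_out, double& ares_out) {
  int nc = m.nc, ns = m.ns;
  std::vector<double> X0;
  StateEval st = eval_state(m, T, V, x, X0);
  P_out = st.P; ares_out = st.ares;
  std::vector<double> ai(nc);
  for (int i = 0; i < nc; ++i) ai[i] = soave_a(m.a0[i], m.c1[i], m.tc[i], T);
  double b = st.bmix, a = st.amix, rho = 1.0 / V;
  double Z = st.P * V / (RGAS * T);
  std::vector<double> lnphi(nc);
  for (int i = 0; i < nc; ++i) {
    double Dp = 0.0;
    for (int j = 0; j < nc; ++j)
      Dp += 2.0 * x[j] * std::sqrt(ai[i] * ai[j]) * (1.0 - m.kij_at(i, j));
    double t1 = -std::log(1.0 - b / V) + m.b[i] / (V - b);
    double t2 = -(1.0 / (RGAS * T)) *
                ((Dp * b - a * m.b[i]) / (b * b) * std::log(1.0 + b / V) +
                 (a / b) * (m.b[i] / V) / (1.0 + b / V));
    double t3 = 0.0;
    if (ns > 0) {
      for (int s = 0; s < ns; ++s)
        if (m.site_comp[s] == i) t3 += m.site_mult[s] * std::log(st.X[s]);
      double dlng_dni = st.g * 1.9 * m.b[i] * rho / 4.0;
      t3 -= 0.5 * st.h * dlng_dni;
    }
    lnphi[i] = t1 + t2 + t3 - std::log(Z);
  }
  return lnphi;
}

// [[Rcpp::export]]
List cpp_lnphi_TV(List mix, double T, double V, NumericVector x) {
  MixData m = unpack(mix);
  std::vector<double> xv(x.begin(), x.end());
  double P, ares;
  std::vector<double> lp = lnphi_at_V(m, T, V, xv, P, ares);
  return List::create(_["lnphi"] = wrap(lp), _["P"] = P, _["ares"] = ares,
                      _["Z"] = P * V / (RGAS * T));
}

// [[Rcpp::export]]
List cpp_lnphi(List mix, double T, double P, NumericVector x, int hint) {
  MixData m = unpack(mix);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> roots = volume_roots(m, T, P, xv);
  if (roots.empty())
    return List::create(_["lnphi"] = NumericVector(0), _["V"] = NA_REAL,
                        _["nroots"] = 0);
  double V;
  if (roots.size() == 1) V = roots[0];
  else if (hint == 1) V = roots.front();
  else if (hint == 2) V = roots.back();
  else {
    double gl = gibbs_res(m, T, roots.front(), P, xv);
    double gv = gibbs_res(m, T, roots.back(), P, xv);
    V = (gl < gv - 1e-12) ? roots.front() : roots.back();
  }
  double Pc, ares;
  std::vector<double> lp = lnphi_at_V(m, T, V, xv, Pc, ares);
  // recompute lnZ with the requested pressure (identical to Pc at a root)
  double Z = P * V / (RGAS * T);
  double Zc = Pc * V / (RGAS * T);
  for (int i = 0; i < m.nc; ++i) lp[i] += std::log(Zc) - std::log(Z);
  return List::create(_["lnphi"] = wrap(lp), _["V"] = V, _["Z"] = Z,
                      _["nroots"] = (int)roots.size(), _["ares"] = ares);
}
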