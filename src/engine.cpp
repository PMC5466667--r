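// Simulation engines for the protocell model.
//
// A "compiled system" (built by compile_system() in R) is a plain list
// of matrices/vectors describing the mass-action network, the
// transport parameters, the lipid-exchange channels and the geometry
// rules. Two engines consume it:
//   - an adaptive Dormand-Prince RK45 integrator with bisection event
//     location on the reduced surface (division / burst), and
//   - an exact direct-method Gillespie SSA with the same event logic
//     and binomial partitioning at division.
//
// State layout: y[0..n_sp-1] = aqueous molecule counts;
// in protocell mode y[n_sp] = N_l (membrane), y[n_sp+1] = N_L.
// Time unit: hours. Volume: m^3. Concentration: mol/m^3.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NAV = 6.02214076e23;

struct Sys {
  int n_sp, n_rxn;
  IntegerMatrix nu_r, nu_p;      // n_sp x n_rxn
  IntegerVector cat;             // 0-based catalyst index, -1 = none
  NumericVector k;               // per hour, conc units mol/m^3
  IntegerVector perm_class;      // 0 impermeable, 1 constant, 2 comp-dep
  NumericVector base_P;          // m/s
  NumericVector env;             // mol/m^3
  IntegerVector osmo;            // 0/1
  NumericVector chi_x, chi_f, chi_w;  // permeability curve (barycentric)
  int aqL;                       // aqueous-L index, -1 if no lipid module
  double alpha_l, alpha_L;       // head areas in m^2
  double k_in;                   // m/s
  double k_out, k_d;             // per hour
  double c_l_env;                // mol/m^3
  double C_out;                  // mol/m^3
  double phi_divide, eps_burst;
  int mode;                      // 0 = fixed compartment, 1 = protocell
  double fixedV, fixedS, fixed_chi;
  bool lipids;                   // membrane dynamics active
};

static Sys parse_sys(const List& s) {
  Sys q;
  q.nu_r = as<IntegerMatrix>(s["nu_r"]);
  q.nu_p = as<IntegerMatrix>(s["nu_p"]);
  q.n_sp = q.nu_r.nrow();
  q.n_rxn = q.nu_r.ncol();
  q.cat = as<IntegerVector>(s["cat"]);
  q.k = as<NumericVector>(s["k"]);
  q.perm_class = as<IntegerVector>(s["perm_class"]);
  q.base_P = as<NumericVector>(s["base_P"]);
  q.env = as<NumericVector>(s["env"]);
  q.osmo = as<IntegerVector>(s["osmo"]);
  q.chi_x = as<NumericVector>(s["chi_x"]);
  q.chi_f = as<NumericVector>(s["chi_f"]);
  q.chi_w = as<NumericVector>(s["chi_w"]);
  q.aqL = as<int>(s["aqL"]);
  q.alpha_l = as<double>(s["alpha_l"]);
  q.alpha_L = as<double>(s["alpha_L"]);
  q.k_in = as<double>(s["k_in"]);
  q.k_out = as<double>(s["k_out"]);
  q.k_d = as<double>(s["k_d"]);
  q.c_l_env = as<double>(s["c_l_env"]);
  q.C_out = as<double>(s["C_out"]);
  q.phi_divide = as<double>(s["phi_divide"]);
  q.eps_burst = as<double>(s["eps_burst"]);
  q.mode = as<int>(s["mode"]);
  q.fixedV = as<double>(s["fixedV"]);
  q.fixedS = as<double>(s["fixedS"]);
  q.fixed_chi = as<double>(s["fixed_chi"]);
  q.lipids = as<bool>(s["lipids"]);
  return q;
}

static double curve_eval(const Sys& q, double x) {
  int n = q.chi_x.size();
  double num = 0.0, den = 0.0;
  for (int j = 0; j < n; ++j) {
    double d = x - q.chi_x[j];
    if (std::fabs(d) < 1e-14) return q.chi_f[j];
    double t = q.chi_w[j] / d;
    num += t * q.chi_f[j];
    den += t;
  }
  return num / den;
}

struct Geom { double V, S, chi, phi; };

static Geom geometry(const Sys& q, const std::vector<double>& y) {
  Geom g;
  if (q.mode == 0) {
    g.V = q.fixedV; g.S = q.fixedS; g.chi = q.fixed_chi;
  } else {
    double tot = 0.0;
    for (int i = 0; i < q.n_sp; ++i)
      if (q.osmo[i]) tot += std::max(y[i], 0.0);
    g.V = tot / (NAV * q.C_out);
    double Nl = std::max(y[q.n_sp], 0.0), NL = std::max(y[q.n_sp + 1], 0.0);
    double s = (Nl * q.alpha_l + NL * q.alpha_L) / 2.0;
    g.S = s;
    g.chi = (s > 0) ? NL * q.alpha_L / (2.0 * s) : 0.0;
  }
  g.phi = (g.V > 0 && g.S > 0)
    ? g.S / std::cbrt(36.0 * M_PI * g.V * g.V) : 0.0;
  return g;
}

// deterministic right-hand side, dy/dt in molecules per hour
static void rhs(const Sys& q, const std::vector<double>& y,
                std::vector<double>& dy) {
  Geom g = geometry(q, y);
  int ny = (int)y.size();
  for (int i = 0; i < ny; ++i) dy[i] = 0.0;
  double VN = g.V * NAV;

  // mass-action reactions
  for (int j = 0; j < q.n_rxn; ++j) {
    double rate = q.k[j];  // mol/m^3/h
    if (q.cat[j] >= 0) rate *= std::max(y[q.cat[j]], 0.0) / VN;
    for (int i = 0; i < q.n_sp; ++i) {
      int s = q.nu_r(i, j);
      if (s > 0) {
        double c = std::max(y[i], 0.0) / VN;
        for (int r = 0; r < s; ++r) rate *= c;
      }
    }
    double flux = rate * VN;  // molecules per hour
    for (int i = 0; i < q.n_sp; ++i)
      dy[i] += (q.nu_p(i, j) - q.nu_r(i, j)) * flux;
  }

  // passive transport
  double fmult = curve_eval(q, g.chi);
  for (int i = 0; i < q.n_sp; ++i) {
    if (q.perm_class[i] == 0) continue;
    double P = q.base_P[i] * (q.perm_class[i] == 2 ? fmult : 1.0);
    double Ph = P * 3600.0;
    dy[i] += Ph * g.S * q.env[i] * NAV
           - Ph * g.S * std::max(y[i], 0.0) / g.V;
  }

  // lipid exchange (protocell mode with lipid module)
  if (q.mode == 1 && q.lipids) {
    double kin_h = q.k_in * 3600.0;
    double Nl = std::max(y[q.n_sp], 0.0), NL = std::max(y[q.n_sp + 1], 0.0);
    double uptake = kin_h * g.S * q.c_l_env * NAV;
    double release = q.k_out * Nl;
    double insertion = (q.aqL >= 0)
      ? kin_h * g.S * std::max(y[q.aqL], 0.0) / g.V : 0.0;
    double displ = q.k_d * NL;
    dy[q.n_sp] += uptake - release + displ;
    dy[q.n_sp + 1] += insertion - displ;
    if (q.aqL >= 0) dy[q.aqL] -= insertion;
  }
}

// [[Rcpp::export]]
NumericVector cpp_rhs(List sys, NumericVector y) {
  Sys q = parse_sys(sys);
  std::vector<double> yv(y.begin(), y.end()), dy(y.size());
  rhs(q, yv, dy);
  return NumericVector(dy.begin(), dy.end());
}

// ---- Dormand-Prince 5(4) ----------------------------------------------

static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
  c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
  a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
  a63 = 46732.0 / 5247, a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
  b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
  e4 = 71.0 / 1920, e5 = -17253.0 / 339200, e6 = 22.0 / 525,
  e7 = -1.0 / 40;

// one DP step of size h from y; returns error norm, fills ynew and k1out
static double dp_step(const Sys& q, const std::vector<double>& y,
                      const std::vector<double>& k1, double h,
                      std::vector<double>& ynew, std::vector<double>& k7,
                      double atol, double rtol) {
  int n = (int)y.size();
  std::vector<double> k2(n), k3(n), k4(n), k5(n), k6(n), tmp(n);
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * a21 * k1[i];
  rhs(q, tmp, k2);
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(q, tmp, k3);
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(q, tmp, k4);
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                         a54 * k4[i]);
  rhs(q, tmp, k5);
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                         a64 * k4[i] + a65 * k5[i]);
  rhs(q, tmp, k6);
  for (int i = 0; i < n; ++i)
    ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
  rhs(q, ynew, k7);
  double err = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                    e6 * k6[i] + e7 * k7[i]);
    double sc = atol + rtol * std::max(std::fabs(y[i]),
                                       std::fabs(ynew[i]));
    double r = e / sc;
    err += r * r;
  }
  return std::sqrt(err / n);
}

// [[Rcpp::export]]
List cpp_integrate(List sys, NumericVector y0, double t0, double t1,
                   int n_out, double rtol, double atol,
                   double max_steps, bool events, bool halve_on_divide) {
  Sys q = parse_sys(sys);
  int n = y0.size();
  std::vector<double> y(y0.begin(), y0.end()), k1(n), k7(n), ynew(n);

  NumericVector out_t(n_out);
  NumericMatrix out_y(n_out, n);
  NumericMatrix out_g(n_out, 4);  // V, S, chi, phi
  for (int i = 0; i < n_out; ++i)
    out_t[i] = t0 + (t1 - t0) * i / std::max(n_out - 1, 1);

  std::vector<double> ev_t, ev_interval;
  std::vector<std::vector<double> > ev_state;
  std::vector<double> ev_chi, ev_V, ev_S;
  double last_div_t = t0;
  std::string outcome = "completed";

  double t = t0;
  int iout = 0;
  rhs(q, y, k1);
  {
    Geom g = geometry(q, y);
    while (iout < n_out && out_t[iout] <= t + 1e-15) {
      for (int i = 0; i < n; ++i) out_y(iout, i) = y[i];
      out_g(iout, 0) = g.V; out_g(iout, 1) = g.S;
      out_g(iout, 2) = g.chi; out_g(iout, 3) = g.phi;
      ++iout;
    }
  }

  double h = (t1 - t0) / 1000.0;
  double hmin = (t1 - t0) * 1e-14;
  long nsteps = 0;
  bool stop_all = false;

  while (t < t1 && !stop_all) {
    if (++nsteps > (long)max_steps) { outcome = "max_steps"; break; }
    if (t + h > t1) h = t1 - t;
    double err = dp_step(q, y, k1, h, ynew, k7, atol, rtol);
    if (err > 1.0 && h > hmin) {  // reject
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
      continue;
    }
    double t_new = t + h;
    std::vector<double> y_acc = ynew, k7_acc = k7;

    // event detection on the reduced surface
    if (events && q.mode == 1) {
      Geom g1 = geometry(q, y_acc);
      int kind = 0;
      if (g1.phi >= q.phi_divide) kind = 1;
      else if (g1.phi <= 1.0 - q.eps_burst) kind = 2;
      if (kind != 0) {
        // bisection on the step fraction for the crossing time
        double lo = 0.0, hi = 1.0;
        std::vector<double> ylo = y, yhi = y_acc, ymid(n), kmid(n);
        for (int it = 0; it < 60; ++it) {
          double mid = 0.5 * (lo + hi);
          dp_step(q, y, k1, h * mid, ymid, kmid, atol, rtol);
          Geom gm = geometry(q, ymid);
          bool crossed = (kind == 1) ? (gm.phi >= q.phi_divide)
                                     : (gm.phi <= 1.0 - q.eps_burst);
          if (crossed) { hi = mid; yhi = ymid; }
          else { lo = mid; ylo = ymid; }
          if (hi - lo < 1e-12) break;
        }
        t_new = t + h * hi;
        y_acc = yhi;
        Geom ge = geometry(q, y_acc);
        if (kind == 2) {
          outcome = "burst";
          stop_all = true;
        } else {
          ev_t.push_back(t_new);
          ev_interval.push_back(t_new - last_div_t);
          ev_state.push_back(y_acc);
          ev_chi.push_back(ge.chi); ev_V.push_back(ge.V);
          ev_S.push_back(ge.S);
          last_div_t = t_new;
          if (halve_on_divide)
            for (int i = 0; i < n; ++i) y_acc[i] *= 0.5;
        }
        rhs(q, y_acc, k7_acc);  // FSAL invalidated by the event
      }
    }

    // record output grid points inside (t, t_new] by cubic Hermite
    while (iout < n_out && out_t[iout] <= t_new + 1e-15) {
      double th = out_t[iout];
      std::vector<double> yi(n);
      if (th >= t_new - 1e-15) {
        yi = y_acc;
      } else {
        double s = (th - t) / (t_new - t);
        double hh = t_new - t;
        // delta form: exact for constant solutions
        double h10 = s * (1 - s) * (1 - s);
        double h01 = s * s * (3 - 2 * s);
        double h11 = s * s * (s - 1);
        for (int i = 0; i < n; ++i)
          yi[i] = y[i] + h01 * (y_acc[i] - y[i]) +
                  hh * (h10 * k1[i] + h11 * k7_acc[i]);
      }
      Geom gi = geometry(q, yi);
      for (int i = 0; i < n; ++i) out_y(iout, i) = yi[i];
      out_g(iout, 0) = gi.V; out_g(iout, 1) = gi.S;
      out_g(iout, 2) = gi.chi; out_g(iout, 3) = gi.phi;
      ++iout;
    }

    t = t_new;
    y = y_acc;
    k1 = k7_acc;
    double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    h *= std::min(5.0, std::max(0.2, fac));
    if ((nsteps & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // pad any remaining grid points (burst / max_steps) with last state
  Geom gl = geometry(q, y);
  int n_recorded = iout;
  for (; iout < n_out; ++iout) {
    for (int i = 0; i < n; ++i) out_y(iout, i) = y[i];
    out_g(iout, 0) = gl.V; out_g(iout, 1) = gl.S;
    out_g(iout, 2) = gl.chi; out_g(iout, 3) = gl.phi;
  }

  int ndiv = (int)ev_t.size();
  NumericMatrix ev_states(ndiv, n);
  for (int j = 0; j < ndiv; ++j)
    for (int i = 0; i < n; ++i) ev_states(j, i) = ev_state[j][i];

  return List::create(
    _["times"] = out_t, _["y"] = out_y, _["geom"] = out_g,
    _["n_recorded"] = n_recorded,
    _["div_t"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["div_interval"] = NumericVector(ev_interval.begin(),
                                      ev_interval.end()),
    _["div_chi"] = NumericVector(ev_chi.begin(), ev_chi.end()),
    _["div_V"] = NumericVector(ev_V.begin(), ev_V.end()),
    _["div_S"] = NumericVector(ev_S.begin(), ev_S.end()),
    _["div_states"] = ev_states,
    _["t_end"] = t, _["outcome"] = outcome, _["nsteps"] = (double)nsteps);
}

// ---- exact SSA (direct method) ----------------------------------------

// falling factorial N (N-1) ... (N-s+1)
static double falling(double N, int s) {
  double r = 1.0;
  for (int i = 0; i < s; ++i) r *= std::max(N - i, 0.0);
  return r;
}

// [[Rcpp::export]]
List cpp_ssa(List sys, NumericVector y0, double t0, double t_end,
             int n_out, double max_events, bool events) {
  Sys q = parse_sys(sys);
  int n = y0.size();
  std::vector<double> y(y0.begin(), y0.end());

  int n_trans = 0;
  std::vector<int> trans_sp;
  for (int i = 0; i < q.n_sp; ++i)
    if (q.perm_class[i] != 0) trans_sp.push_back(i);
  n_trans = (int)trans_sp.size();
  int n_lip = (q.mode == 1 && q.lipids) ? 4 : 0;
  int n_ch = q.n_rxn + 2 * n_trans + n_lip;
  std::vector<double> a(n_ch);
  std::vector<int> rxn_order(q.n_rxn);
  // sparse reactant lists and net-change lists per reaction
  std::vector<std::vector<std::pair<int, int> > > r_in(q.n_rxn),
    r_net(q.n_rxn);
  for (int j = 0; j < q.n_rxn; ++j) {
    int ord = (q.cat[j] >= 0) ? 1 : 0;
    for (int i = 0; i < q.n_sp; ++i) {
      int s = q.nu_r(i, j);
      ord += s;
      if (s > 0) r_in[j].push_back(std::make_pair(i, s));
      int d = q.nu_p(i, j) - s;
      if (d != 0) r_net[j].push_back(std::make_pair(i, d));
    }
    rxn_order[j] = ord;
  }
  // per-species transport prefactors (constant parts)
  std::vector<double> influx_pref(q.n_sp), efflux_pref(q.n_sp);
  for (int i = 0; i < q.n_sp; ++i) {
    double Ph = q.base_P[i] * 3600.0;
    influx_pref[i] = Ph * q.env[i] * NAV;
    efflux_pref[i] = Ph;
  }

  NumericVector out_t(n_out);
  NumericMatrix out_y(n_out, n);
  NumericMatrix out_g(n_out, 4);
  for (int i = 0; i < n_out; ++i)
    out_t[i] = t0 + (t_end - t0) * i / std::max(n_out - 1, 1);

  std::vector<double> dv_t, dv_interval, dv_chi, dv_V, dv_S;
  std::vector<std::vector<double> > dv_mother, dv_d1, dv_d2;
  std::vector<int> dv_follow;
  double last_div_t = t0;
  std::string outcome = "completed";
  double max_iso_dev = 0.0;
  double t = t0;
  double n_events = 0;
  int iout = 0;

  Geom g = geometry(q, y);
  double kin_h = q.k_in * 3600.0;
  while (true) {
    // propensities (per hour)
    double VN = g.V * NAV;
    double invVN = 1.0 / VN;
    double fmult = curve_eval(q, g.chi);
    int c = 0;
    for (int j = 0; j < q.n_rxn; ++j) {
      double prop = q.k[j];
      for (int o = 1; o < rxn_order[j]; ++o) prop *= invVN;
      if (q.cat[j] >= 0) prop *= y[q.cat[j]];
      const std::vector<std::pair<int, int> >& rj = r_in[j];
      for (size_t m = 0; m < rj.size(); ++m)
        prop *= falling(y[rj[m].first], rj[m].second);
      a[c++] = prop;
    }
    for (int kk = 0; kk < n_trans; ++kk) {
      int i = trans_sp[kk];
      double fm = (q.perm_class[i] == 2) ? fmult : 1.0;
      a[c++] = fm * influx_pref[i] * g.S;              // influx
      a[c++] = fm * efflux_pref[i] * g.S * y[i] / g.V; // efflux
    }
    if (n_lip) {
      a[c++] = kin_h * g.S * q.c_l_env * NAV;              // l uptake
      a[c++] = q.k_out * y[q.n_sp];                        // l release
      a[c++] = (q.aqL >= 0)
        ? kin_h * g.S * y[q.aqL] / g.V : 0.0;              // L insertion
      a[c++] = q.k_d * y[q.n_sp + 1];                      // displacement
    }
    double a0 = 0.0;
    for (int j = 0; j < n_ch; ++j) a0 += a[j];

    double t_next = (a0 > 0)
      ? t - std::log(unif_rand()) / a0
      : t_end + 1.0;

    // flush output grid up to the event time
    while (iout < n_out && out_t[iout] <= std::min(t_next, t_end)) {
      for (int i = 0; i < n; ++i) out_y(iout, i) = y[i];
      out_g(iout, 0) = g.V; out_g(iout, 1) = g.S;
      out_g(iout, 2) = g.chi; out_g(iout, 3) = g.phi;
      ++iout;
    }
    if (t_next > t_end) { t = t_end; break; }
    t = t_next;

    // choose and fire a channel
    double r = unif_rand() * a0, acc = 0.0;
    int ch = n_ch - 1;
    for (int j = 0; j < n_ch; ++j) {
      acc += a[j];
      if (r <= acc) { ch = j; break; }
    }
    if (ch < q.n_rxn) {
      const std::vector<std::pair<int, int> >& nj = r_net[ch];
      for (size_t m = 0; m < nj.size(); ++m) {
        y[nj[m].first] += nj[m].second;
        if (y[nj[m].first] < 0)
          stop("internal inconsistency: negative count fired");
      }
    } else if (ch < q.n_rxn + 2 * n_trans) {
      int kk = (ch - q.n_rxn) / 2;
      int dir = (ch - q.n_rxn) % 2;   // 0 influx, 1 efflux
      y[trans_sp[kk]] += (dir == 0) ? 1 : -1;
      if (y[trans_sp[kk]] < 0)
        stop("internal inconsistency: negative count fired");
    } else {
      int lc = ch - q.n_rxn - 2 * n_trans;
      if (lc == 0) y[q.n_sp] += 1;                         // l uptake
      else if (lc == 1) y[q.n_sp] -= 1;                    // l release
      else if (lc == 2) { y[q.aqL] -= 1; y[q.n_sp + 1] += 1; }
      else { y[q.n_sp + 1] -= 1; y[q.n_sp] += 1; }         // L -> l swap
      if (y[q.n_sp] < 0 || y[q.n_sp + 1] < 0 ||
          (q.aqL >= 0 && y[q.aqL] < 0))
        stop("internal inconsistency: negative count fired");
    }
    n_events += 1;

    g = geometry(q, y);
    // isotonic contract bookkeeping
    if (q.mode == 1) {
      double tot = 0.0;
      for (int i = 0; i < q.n_sp; ++i) if (q.osmo[i]) tot += y[i];
      double cin = tot / (g.V * NAV);
      double dev = std::fabs(cin - q.C_out) / q.C_out;
      if (dev > max_iso_dev) max_iso_dev = dev;
    }

    if (events && q.mode == 1) {
      if (g.phi >= q.phi_divide) {
        std::vector<double> d1(n), d2(n);
        for (int i = 0; i < q.n_sp; ++i) {
          d1[i] = R::rbinom(y[i], 0.5);
          d2[i] = y[i] - d1[i];
        }
        for (int i = q.n_sp; i < n; ++i) {  // membrane lipids: even split
          double half = std::floor(y[i] / 2.0);
          double rem = y[i] - 2 * half;
          double extra = (rem > 0 && unif_rand() < 0.5) ? 1.0 : 0.0;
          d1[i] = half + (rem > 0 ? extra : 0.0);
          d2[i] = y[i] - d1[i];
        }
        int follow = (unif_rand() < 0.5) ? 1 : 2;
        dv_t.push_back(t);
        dv_interval.push_back(t - last_div_t);
        dv_chi.push_back(g.chi); dv_V.push_back(g.V); dv_S.push_back(g.S);
        dv_mother.push_back(y);
        dv_d1.push_back(d1); dv_d2.push_back(d2);
        dv_follow.push_back(follow);
        last_div_t = t;
        y = (follow == 1) ? d1 : d2;
        g = geometry(q, y);
      } else if (g.phi <= 1.0 - q.eps_burst) {
        outcome = "burst";
        break;
      }
    }
    if (n_events >= max_events) { outcome = "max_events"; break; }
    if (((long)n_events & 16383) == 0) Rcpp::checkUserInterrupt();
  }

  int n_recorded = iout;
  for (; iout < n_out; ++iout) {
    for (int i = 0; i < n; ++i) out_y(iout, i) = y[i];
    out_g(iout, 0) = g.V; out_g(iout, 1) = g.S;
    out_g(iout, 2) = g.chi; out_g(iout, 3) = g.phi;
  }

  int ndiv = (int)dv_t.size();
  NumericMatrix m_mother(ndiv, n), m_d1(ndiv, n), m_d2(ndiv, n);
  for (int j = 0; j < ndiv; ++j)
    for (int i = 0; i < n; ++i) {
      m_mother(j, i) = dv_mother[j][i];
      m_d1(j, i) = dv_d1[j][i];
      m_d2(j, i) = dv_d2[j][i];
    }

  return List::create(
    _["times"] = out_t, _["y"] = out_y, _["geom"] = out_g,
    _["n_recorded"] = n_recorded,
    _["div_t"] = NumericVector(dv_t.begin(), dv_t.end()),
    _["div_interval"] = NumericVector(dv_interval.begin(),
                                      dv_interval.end()),
    _["div_chi"] = NumericVector(dv_chi.begin(), dv_chi.end()),
    _["div_V"] = NumericVector(dv_V.begin(), dv_V.end()),
    _["div_S"] = NumericVector(dv_S.begin(), dv_S.end()),
    _["div_mother"] = m_mother, _["div_daughter1"] = m_d1,
    _["div_daughter2"] = m_d2,
    _["div_follow"] = IntegerVector(dv_follow.begin(), dv_follow.end()),
    _["final_state"] = NumericVector(y.begin(), y.end()),
    _["t_end"] = t, _["outcome"] = outcome,
    _["n_events"] = n_events, _["max_iso_dev"] = max_iso_dev);
}
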