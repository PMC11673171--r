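// Single-pass initial value problem for the amount-removed variable chi.
//
// chi(z) = Qb(z) Cstlb(z) - Qb_in Cstlb_in = Qd(z) Cstld(z) - Qd_in Cstld_out,
// with chi = 0 at the blood inlet (z = 0) and chi = xy0 at the dialysate
// inlet (z = L). For a guessed xy0 the IVP is integrated from z = L down to
// z = 0 (starting at the dialysate inlet keeps the state bounded and the
// stiffness mild) and the residual Delta = chi(0) is returned.
//
// The integrator is an A-stable implicit trapezoid scheme on a fixed grid
// (node spacing = requested max spatial step) with a damped Newton inner
// iteration; non-convergence, non-finite state or physically impossible
// reconstructed concentrations mark the guess as unstable rather than
// raising: instability is data for the interval classifier.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// stable physical root of the single-site binding quadratic
static inline double free_conc(double ct, double ca, double KB) {
  if (ct <= 0.0) return 0.0;
  double b = ca + 1.0 / KB - ct;
  double q = ct / KB;
  double s = std::sqrt(b * b + 4.0 * q);
  double cs = (b > 0.0) ? (2.0 * q / (b + s)) : ((s - b) / 2.0);
  if (cs < 0.0) cs = 0.0;
  if (cs > ct) cs = ct;
  return cs;
}

static inline double f_of_pe(double pe) {
  if (std::fabs(pe) < 1e-6) return 0.5 - pe / 12.0;
  return 1.0 / pe - 1.0 / std::expm1(pe);
}

struct PassParams {
  // node arrays along z (length n_nodes, uniform spacing h, z[0] = 0)
  NumericVector Qb, Qd, Jv_m, Catlb, Catld; // flows mL/min, Jv mL/min/m, conc M
  double h, L, sigma, kA, KB;
  double Qb_in, Cb_in, Qd_in, Cd_in;
};

// d(chi)/dz at node i for state chi; sets *ok = false on unphysical state
static inline double rhs(const PassParams &p, int i, double chi,
                         double Cd_out, bool *ok) {
  double qb = p.Qb[i], qd = p.Qd[i];
  double cstlb = (p.Qb_in * p.Cb_in + chi) / qb;
  double cstld = (chi + Cd_out * p.Qd_in) / qd;
  double scale = p.Cb_in + p.Cd_in + 1e-300;
  if (!std::isfinite(cstlb) || !std::isfinite(cstld) ||
      cstlb < -1e-9 * scale || cstld < -1e-9 * scale ||
      cstlb > 1e6 * scale || cstld > 1e6 * scale) {
    *ok = false;
    return 0.0;
  }
  if (cstlb < 0.0) cstlb = 0.0;
  if (cstld < 0.0) cstld = 0.0;
  double csb = free_conc(cstlb, p.Catlb[i], p.KB);
  double csd = free_conc(cstld, p.Catld[i], p.KB);
  double dC = csb - csd;
  double kA_L = p.kA / p.L;
  double jv = p.Jv_m[i];                       // mL/min per m
  double jc = 1e3 * 1e-5 * std::min(qb, qd);   // crit flux per m
  if (std::fabs(jv) < jc || p.sigma == 1.0) {
    return -kA_L * dC;
  }
  double conv = jv * (1.0 - p.sigma);
  double f;
  if (p.kA > 0.0) {
    f = f_of_pe(jv * (1.0 - p.sigma) * p.L / p.kA);
  } else {
    f = (jv > 0.0) ? 0.0 : 1.0;
  }
  double up = (jv > 0.0) ? csb : csd;
  return (conv * f - kA_L) * dC - conv * up;
}

// integrate chi from z = L (chi = xy0) to z = 0; returns chi(0), *stable,
// optionally stores the profile (chi at every node, index 0 = z = 0)
static double integrate_pass(const PassParams &p, double xy0, bool *stable,
                             NumericVector *profile) {
  int n = p.Qb.size();
  double Cd_out = p.Cd_in - xy0 / p.Qd_in;
  double chi = xy0;
  double amount_scale = std::fabs(p.Qb_in * p.Cb_in) +
                        std::fabs(p.Qd_in * p.Cd_in) + std::fabs(xy0) + 1e-300;
  *stable = true;
  if (profile) (*profile)[n - 1] = chi;
  bool ok = true;
  double g_here = rhs(p, n - 1, chi, Cd_out, &ok);
  if (!ok) { *stable = false; return NA_REAL; }
  double Fp = 1.0;          // chord slope, refreshed once per step
  for (int i = n - 1; i > 0; --i) {
    // implicit trapezoid step from node i to node i-1 (step -h);
    // chord Newton: the Jacobian is evaluated once per step and reused
    double x = chi - p.h * g_here;  // explicit Euler predictor
    bool converged = false;
    double g_next = 0.0;
    for (int it = 0; it < 12; ++it) {
      bool ok1 = true;
      g_next = rhs(p, i - 1, x, Cd_out, &ok1);
      if (!ok1 || !std::isfinite(x)) { *stable = false; return NA_REAL; }
      double F = x - chi + 0.5 * p.h * (g_here + g_next);
      if (it == 0) {
        double dx = std::max(1e-7 * amount_scale, std::fabs(x) * 1e-7);
        bool ok2 = true;
        double gp = rhs(p, i - 1, x + dx, Cd_out, &ok2);
        Fp = ok2 ? (1.0 + 0.5 * p.h * (gp - g_next) / dx) : 1.0;
        if (!std::isfinite(Fp) || std::fabs(Fp) < 1e-12) Fp = 1.0;
      }
      double step = F / Fp;
      x -= step;
      if (std::fabs(step) < 1e-12 * amount_scale + 1e-11 * std::fabs(x)) {
        converged = true;
        break;
      }
    }
    if (!converged || !std::isfinite(x)) { *stable = false; return NA_REAL; }
    bool okf = true;
    g_here = rhs(p, i - 1, x, Cd_out, &okf);
    if (!okf) { *stable = false; return NA_REAL; }
    chi = x;
    if (profile) (*profile)[i - 1] = chi;
  }
  if (!std::isfinite(chi) || std::fabs(chi) > 1e6 * amount_scale) {
    *stable = false;
    return NA_REAL;
  }
  return chi;
}

static PassParams make_params(List pass) {
  PassParams p;
  p.Qb = as<NumericVector>(pass["Qb"]);
  p.Qd = as<NumericVector>(pass["Qd"]);
  p.Jv_m = as<NumericVector>(pass["Jv_m"]);
  p.Catlb = as<NumericVector>(pass["Catlb"]);
  p.Catld = as<NumericVector>(pass["Catld"]);
  p.h = as<double>(pass["h"]);
  p.L = as<double>(pass["L"]);
  p.sigma = as<double>(pass["sigma"]);
  p.kA = as<double>(pass["kA"]);
  p.KB = as<double>(pass["KB"]);
  p.Qb_in = as<double>(pass["Qb_in"]);
  p.Cb_in = as<double>(pass["Cb_in"]);
  p.Qd_in = as<double>(pass["Qd_in"]);
  p.Cd_in = as<double>(pass["Cd_in"]);
  return p;
}

// [[Rcpp::export(name = ".shoot_batch_cpp")]]
List shoot_batch_cpp(List pass, NumericVector guesses) {
  PassParams p = make_params(pass);
  int m = guesses.size();
  NumericVector delta(m);
  LogicalVector stable(m);
  for (int j = 0; j < m; ++j) {
    bool st = true;
    delta[j] = integrate_pass(p, guesses[j], &st, nullptr);
    stable[j] = st;
  }
  return List::create(_["delta"] = delta, _["stable"] = stable);
}

// [[Rcpp::export(name = ".shoot_profile_cpp")]]
List shoot_profile_cpp(List pass, double xy0) {
  PassParams p = make_params(pass);
  int n = p.Qb.size();
  NumericVector profile(n);
  bool st = true;
  double d = integrate_pass(p, xy0, &st, &profile);
  return List::create(_["delta"] = d, _["stable"] = st, _["chi"] = profile);
}
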