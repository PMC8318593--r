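#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout: y = (RP, IP, RRP, Exo) in vesicle units.
// Parameter layout (fixed order shared with R/params.R):
//   0 r_max, 1 i_max, 2 e_max, 3 k, 4 x0, 5 IP_max, 6 RRP_max, 7 RP_max, 8 d_max

struct RibbonP {
  double r_max, i_max, e_max, k, x0, IP_max, RRP_max, RP_max, d_max;
  explicit RibbonP(const NumericVector &p)
      : r_max(p[0]), i_max(p[1]), e_max(p[2]), k(p[3]), x0(p[4]),
        IP_max(p[5]), RRP_max(p[6]), RP_max(p[7]), d_max(p[8]) {}
};

static inline double sigmoid_f(double ca, double k, double x0) {
  return 1.0 / (1.0 + std::exp(-k * (ca - x0)));
}

// Occupancy-dependent fluxes; the state is clipped to [0, capacity] before the
// flux formulas are evaluated so small solver over/undershoots cannot feed back.
static inline void fluxes(const double y[4], double ca, const RibbonP &p,
                          double f[4]) {
  double RP  = std::min(std::max(y[0], 0.0), p.RP_max);
  double IP  = std::min(std::max(y[1], 0.0), p.IP_max);
  double RRP = std::min(std::max(y[2], 0.0), p.RRP_max);
  double Exo = std::max(y[3], 0.0);
  f[0] = p.r_max * (1.0 - IP / p.IP_max) * (RP / p.RP_max);   // r: RP -> IP
  f[1] = p.i_max * (1.0 - RRP / p.RRP_max) * (IP / p.IP_max); // i: IP -> RRP
  f[2] = p.e_max * sigmoid_f(ca, p.k, p.x0) * (RRP / p.RRP_max); // e: release
  f[3] = p.d_max * Exo;                                       // d: recycling
}

static inline void rhs(const double y[4], double ca, const RibbonP &p,
                       double dy[4]) {
  double f[4];
  fluxes(y, ca, p, f);
  dy[0] = f[3] - f[0];
  dy[1] = f[0] - f[1];
  dy[2] = f[1] - f[2];
  dy[3] = f[2] - f[3];
}

// Linear interpolation of the calcium input on its uniform grid (clamped ends).
struct CaInterp {
  double t0, dt;
  const NumericVector &v;
  CaInterp(double t0_, double dt_, const NumericVector &v_)
      : t0(t0_), dt(dt_), v(v_) {}
  double operator()(double t) const {
    double s = (t - t0) / dt;
    if (s <= 0.0) return v[0];
    int n = v.size();
    if (s >= n - 1) return v[n - 1];
    int j = (int)std::floor(s);
    double w = s - j;
    return v[j] * (1.0 - w) + v[j + 1] * w;
  }
};

// One adaptive Bogacki-Shampine 3(2) segment from t to t_end.
// k1 carries the FSAL derivative; pass k1_valid=false on the first call.
template <class CaFun>
static void integrate_segment(double &t, double t_end, double y[4],
                              const CaFun &ca, const RibbonP &p, double rtol,
                              double atol, double hmax, double k1[4],
                              bool &k1_valid) {
  double h = std::min(hmax, t_end - t);
  const double hmin = 1e-12;
  while (t < t_end - 1e-12) {
    if (!k1_valid) {
      rhs(y, ca(t), p, k1);
      k1_valid = true;
    }
    if (h > t_end - t) h = t_end - t;
    double y2[4], y3[4], ynew[4], k2[4], k3[4], k4[4];
    for (int j = 0; j < 4; ++j) y2[j] = y[j] + 0.5 * h * k1[j];
    rhs(y2, ca(t + 0.5 * h), p, k2);
    for (int j = 0; j < 4; ++j) y3[j] = y[j] + 0.75 * h * k2[j];
    rhs(y3, ca(t + 0.75 * h), p, k3);
    for (int j = 0; j < 4; ++j)
      ynew[j] = y[j] + h * (2.0 / 9.0 * k1[j] + 1.0 / 3.0 * k2[j] +
                            4.0 / 9.0 * k3[j]);
    rhs(ynew, ca(t + h), p, k4);
    // embedded 2nd-order error estimate
    double errnorm = 0.0;
    for (int j = 0; j < 4; ++j) {
      double err = h * (-5.0 / 72.0 * k1[j] + 1.0 / 12.0 * k2[j] +
                        1.0 / 9.0 * k3[j] - 1.0 / 8.0 * k4[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      errnorm = std::max(errnorm, std::fabs(err) / sc);
    }
    bool finite = true;
    for (int j = 0; j < 4; ++j)
      if (!std::isfinite(ynew[j])) finite = false;
    if (!finite)
      stop("ribbon ODE solver produced a non-finite state near t = %f", t);
    if (errnorm <= 1.0) {
      t += h;
      for (int j = 0; j < 4; ++j) {
        y[j] = ynew[j];
        k1[j] = k4[j]; // FSAL
      }
      double fac = (errnorm > 0.0)
                       ? std::min(5.0, std::max(0.2, 0.9 * std::pow(errnorm, -1.0 / 3.0)))
                       : 5.0;
      h = std::min(hmax, h * fac);
    } else {
      double fac = std::max(0.2, 0.9 * std::pow(errnorm, -1.0 / 3.0));
      h *= fac;
      k1_valid = true; // k1 still the derivative at (t, y)
      if (h < hmin)
        stop("ribbon ODE solver step size underflow near t = %f", t);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix ribbon_ode_cpp(double t0, double dt, NumericVector ca,
                             NumericVector params, NumericVector y0,
                             double rtol, double atol) {
  if (ca.size() < 2) stop("calcium trace must have at least 2 samples");
  RibbonP p(params);
  CaInterp cain(t0, dt, ca);
  int n = ca.size();
  NumericMatrix out(n, 8);
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  double k1[4];
  bool k1_valid = false;
  double t = t0;
  for (int irow = 0; irow < n; ++irow) {
    double tt = t0 + irow * dt;
    if (irow > 0)
      integrate_segment(t, tt, y, cain, p, rtol, atol, dt, k1, k1_valid);
    double f[4];
    fluxes(y, cain(tt), p, f);
    out(irow, 0) = y[0];
    out(irow, 1) = y[1];
    out(irow, 2) = y[2];
    out(irow, 3) = y[3];
    out(irow, 4) = f[0];
    out(irow, 5) = f[1];
    out(irow, 6) = f[2];
    out(irow, 7) = f[3];
  }
  colnames(out) = CharacterVector::create("RP", "IP", "RRP", "Exo", "r", "i",
                                          "e", "d");
  return out;
}

// Relax the pools at a constant calcium level until the state stops changing
// (relative change below tol_rel over a 1 s stretch), mimicking the adaptation
// period that precedes each recording. Returns the settled state.
// [[Rcpp::export]]
NumericVector ribbon_burnin_cpp(double ca, NumericVector params,
                                NumericVector y0, double rtol, double atol,
                                double tol_rel, double max_time) {
  RibbonP p(params);
  struct ConstCa {
    double c;
    double operator()(double) const { return c; }
  } cain{ca};
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  double total = y[0] + y[1] + y[2] + y[3];
  double k1[4];
  bool k1_valid = false;
  double t = 0.0;
  const double chunk = 1.0;
  while (t < max_time) {
    double yprev[4] = {y[0], y[1], y[2], y[3]};
    double tend = t + chunk;
    integrate_segment(t, tend, y, cain, p, rtol, atol, 0.05, k1, k1_valid);
    double dmax = 0.0;
    for (int j = 0; j < 4; ++j)
      dmax = std::max(dmax, std::fabs(y[j] - yprev[j]));
    if (dmax / total < tol_rel) break;
  }
  return NumericVector::create(y[0], y[1], y[2], y[3]);
}
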