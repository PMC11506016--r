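// Two-boundary Wiener first-passage-time machinery.
//
// The defective density of absorption at the LOWER boundary of a Wiener
// process with drift v, boundary separation a, relative start w = z/a and
// unit diffusion coefficient is
//
//   f_lower(t | v, a, w) = (1/a^2) * exp(-v*a*w - v^2 t / 2) * f0(t/a^2; w)
//
// where f0 is the standardized (a = 1, v = 0) density.  f0 has two classic
// series representations: a large-time Fourier sine series and a small-time
// image expansion; each converges fast in its own regime, and the number of
// terms needed for a target truncation error is chosen adaptively
// (Navarro & Fuss style bounds).  The upper-boundary density follows by the
// reflection v -> -v, w -> 1 - w.

#include <Rcpp.h>
#include "wiener.h"
using namespace Rcpp;

static const double PI_ = 3.141592653589793238462643383280;

// number of terms needed for the small-time expansion, error < eps
static double ks_terms(double u, double eps) {
  double ks = 2.0;
  if (2.0 * std::sqrt(2.0 * PI_ * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * PI_ * u)));
  }
  double lo = std::sqrt(u) + 1.0;
  return ks > lo ? ks : lo;
}

// number of terms needed for the large-time expansion, error < eps
static double kl_terms(double u, double eps) {
  double kl = 1.0 / (PI_ * std::sqrt(u));
  if (PI_ * u * eps < 1.0) {
    double cand = std::sqrt(-2.0 * std::log(PI_ * u * eps) / (PI_ * PI_ * u));
    if (cand > kl) kl = cand;
  }
  return kl;
}

// standardized density at scaled time u = t/a^2, start w, lower boundary
static double f0_small(double u, double w, int K) {
  double s = 0.0;
  int half = K / 2 + 1;
  for (int k = -half; k <= half; ++k) {
    double wk = w + 2.0 * k;
    s += wk * std::exp(-wk * wk / (2.0 * u));
  }
  return s / std::sqrt(2.0 * PI_ * u * u * u);
}

static double f0_large(double u, double w, int K) {
  double s = 0.0;
  for (int k = 1; k <= K; ++k) {
    s += k * std::exp(-k * k * PI_ * PI_ * u / 2.0) * std::sin(k * PI_ * w);
  }
  return PI_ * s;
}

double wiener_lpdf_one(double t, int upper, double v, double a, double w,
                       double tol, int method) {
  if (!(t > 0.0)) return -INFINITY;
  if (upper) { v = -v; w = 1.0 - w; }
  double u = t / (a * a);
  // log of the multiplier C in f = C * f0(u; w)
  double lmult = -v * a * w - 0.5 * v * v * t - 2.0 * std::log(a);
  // tolerance requested on the final-density scale; convert to f0 scale
  double eps = tol * std::exp(-lmult);
  if (!(eps > 1e-14)) eps = 1e-14;
  if (eps > 1e-2) eps = 1e-2;
  double base;
  if (method == 1) {
    base = f0_small(u, w, (int)std::ceil(ks_terms(u, eps)));
  } else if (method == 2) {
    base = f0_large(u, w, (int)std::ceil(kl_terms(u, eps)));
  } else {
    double ks = ks_terms(u, eps), kl = kl_terms(u, eps);
    base = (ks < kl) ? f0_small(u, w, (int)std::ceil(ks))
                     : f0_large(u, w, (int)std::ceil(kl));
  }
  if (!(base > 0.0)) return -INFINITY;
  return std::log(base) + lmult;
}

double wiener_pdf_one(double t, int upper, double v, double a, double w,
                      double tol, int method) {
  double l = wiener_lpdf_one(t, upper, v, a, w, tol, method);
  if (l == -INFINITY) return 0.0;
  double d = std::exp(l);
  return d > 0.0 ? d : 0.0;
}

double prob_upper_one(double v, double a, double w) {
  double z = w * a;
  if (std::fabs(v) * a < 1e-9) return w;  // zero-drift limit
  // (1 - exp(-2 v z)) / (1 - exp(-2 v a)), stable via expm1
  return std::expm1(-2.0 * v * z) / std::expm1(-2.0 * v * a);
}

// Euler-Maruyama with Brownian-bridge boundary-crossing correction.
int sim_one(Rng &rng, double v, double a, double w, double dt, double tmax,
            double &tdec) {
  double x = w * a, t = 0.0;
  double sdt = std::sqrt(dt);
  while (t < tmax) {
    double x1 = x + v * dt + sdt * rng.norm();
    t += dt;
    if (x1 >= a) { tdec = t; return 1; }
    if (x1 <= 0.0) { tdec = t; return 0; }
    // probability the continuous path crossed a boundary inside the step
    double pu = std::exp(-2.0 * (a - x) * (a - x1) / dt);
    double pl = std::exp(-2.0 * x * x1 / dt);
    double uu = rng.unif();
    if (uu < pu) { tdec = t; return 1; }
    if (uu < pu + pl) { tdec = t; return 0; }
    x = x1;
  }
  tdec = tmax;
  return -1;
}

// [[Rcpp::export]]
NumericVector wiener_pdf_cpp(NumericVector t, LogicalVector upper, double v,
                             double a, double w, double tol, int method) {
  R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int up = upper.size() == 1 ? (int)upper[0] : (int)upper[i];
    out[i] = wiener_pdf_one(t[i], up, v, a, w, tol, method);
  }
  return out;
}

// [[Rcpp::export]]
double prob_upper_cpp(double v, double a, double w) {
  return prob_upper_one(v, a, w);
}

// [[Rcpp::export]]
List sim_trials_cpp(int n, double v, double a, double w, double tau,
                    double dt, double tmax, double seed) {
  Rng rng((std::uint64_t)seed);
  IntegerVector boundary(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    double tdec;
    int side = sim_one(rng, v, a, w, dt, tmax, tdec);
    boundary[i] = side;
    rt[i] = (side < 0) ? NA_REAL : tdec + tau;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}

// [[Rcpp::export]]
double loglik_cpp(NumericVector rt, LogicalVector upper, double v, double a,
                  double w, double tau, double tol) {
  double s = 0.0;
  for (R_xlen_t i = 0; i < rt.size(); ++i) {
    double t = rt[i] - tau;
    if (!(t > 1e-6)) return -INFINITY;
    double l = wiener_lpdf_one(t, (int)upper[i], v, a, w, tol, 0);
    if (l == -INFINITY) return -INFINITY;
    s += l;
  }
  return s;
}

// Simulate a whole trial table in one sweep: one row per scheduled trial with
// its own parameters. Used by the synthetic-study generator and posterior
// predictive checks. rt is NA and boundary -1 when no absorption by tmax.
// [[Rcpp::export]]
List sim_schedule_cpp(NumericVector v, NumericVector a, NumericVector w,
                      NumericVector tau, double dt, double tmax, double seed) {
  R_xlen_t n = v.size();
  Rng rng((std::uint64_t)seed);
  IntegerVector boundary(n);
  NumericVector rt(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double tdec;
    int side = sim_one(rng, v[i], a[i], w[i], dt, tmax - tau[i], tdec);
    boundary[i] = side;
    rt[i] = (side < 0) ? NA_REAL : tdec + tau[i];
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}
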