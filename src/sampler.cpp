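// Adaptive Metropolis-within-Gibbs sampler for the twelve-group hierarchical
// drift-diffusion model.
//
// Structure: each participant p and valence group g has its own drift rate
// v[p,g], boundary separation a[p,g] and non-decision time t0[p,g], drawn from
// group-level Normal(mu_*, sig_*) distributions (one triple of families per
// group).  The relative starting point w is shared across groups within a
// participant: w[p] ~ Normal(mu_w, sig_w), truncated to (0,1); the "no bias"
// variant pins w = 0.5 everywhere.  Group-level means get conjugate or
// Metropolis updates, spreads get log-scale Metropolis updates with
// half-normal priors.  Proposal scales adapt toward 44% acceptance during
// burn-in only, so the post-burn-in chain is a fixed Markov kernel.
//
// The likelihood of a trial is the defective Wiener first-passage density at
// the boundary actually hit, evaluated at rt - t0.  Trials with rt <= t0 have
// zero likelihood and proposals implying them are rejected.

#include <Rcpp.h>
#include <vector>
#include "wiener.h"
using namespace Rcpp;

struct ParBlock {
  std::vector<double> val, step;
  std::vector<int> acc, tries;
  void init(int n, double v0, double s0) {
    val.assign(n, v0); step.assign(n, s0);
    acc.assign(n, 0); tries.assign(n, 0);
  }
};

static inline double ln_norm(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * z * z - std::log(s);
}

static void adapt(std::vector<double> &step, std::vector<int> &acc,
                  std::vector<int> &tries) {
  for (size_t i = 0; i < step.size(); ++i) {
    if (tries[i] == 0) continue;
    double rate = (double)acc[i] / tries[i];
    step[i] *= std::exp(0.66 * (rate - 0.44));
    if (step[i] < 1e-5) step[i] = 1e-5;
    if (step[i] > 10.0) step[i] = 10.0;
    acc[i] = 0; tries[i] = 0;
  }
}

// [[Rcpp::export]]
List ddm_mcmc_cpp(NumericVector rt, LogicalVector upper, IntegerVector pid,
                  IntegerVector cell, int P, int G, bool bias,
                  int n_samples, int burn_in, int thin, double seed,
                  List prior, List inits, double tol) {
  const int N = rt.size();
  // trial indices per participant x group cell
  std::vector<std::vector<int>> idx((size_t)P * G);
  for (int i = 0; i < N; ++i) idx[(size_t)pid[i] + (size_t)P * cell[i]].push_back(i);

  // priors
  const double mu_v_mean = prior["mu_v_mean"], mu_v_sd = prior["mu_v_sd"];
  const double a_shape = prior["a_shape"], a_rate = prior["a_rate"], a_lb = prior["a_lb"];
  const double tau_lb = prior["tau_lb"], tau_ub = prior["tau_ub"];
  const double z_a = prior["z_a"], z_b = prior["z_b"];
  const double ss_v = prior["sig_scale_v"], ss_a = prior["sig_scale_a"];
  const double ss_t = prior["sig_scale_t"], ss_w = prior["sig_scale_w"];

  // hard support bounds for participant-level parameters
  const double V_B = 12.0, A_LO = 0.15, A_HI = 6.0, T_LO = 0.005, T_HI = 2.5;
  const double W_LO = 0.03, W_HI = 0.97, SIG_LO = 1e-3, SIG_HI = 10.0;

  // state
  NumericMatrix iv = inits["v"], ia = inits["a"], it0 = inits["t0"];
  NumericVector iw = inits["w"];
  NumericVector imu_v = inits["mu_v"], isig_v = inits["sig_v"];
  NumericVector imu_a = inits["mu_a"], isig_a = inits["sig_a"];
  NumericVector imu_t = inits["mu_t"], isig_t = inits["sig_t"];
  double mu_w = inits["mu_w"], sig_w = inits["sig_w"];

  ParBlock v, a, t0, w;
  v.init(P * G, 0.0, 0.4); a.init(P * G, 1.8, 0.15);
  t0.init(P * G, 0.3, 0.02); w.init(P, 0.5, 0.05);
  for (int g = 0; g < G; ++g)
    for (int p = 0; p < P; ++p) {
      v.val[p + P * g] = iv(p, g);
      a.val[p + P * g] = ia(p, g);
      t0.val[p + P * g] = it0(p, g);
    }
  for (int p = 0; p < P; ++p) w.val[p] = bias ? iw[p] : 0.5;

  std::vector<double> mu_v(G), sig_v(G), mu_a(G), sig_a(G), mu_t(G), sig_t(G);
  for (int g = 0; g < G; ++g) {
    mu_v[g] = imu_v[g]; sig_v[g] = isig_v[g];
    mu_a[g] = imu_a[g]; sig_a[g] = isig_a[g];
    mu_t[g] = imu_t[g]; sig_t[g] = isig_t[g];
  }
  ParBlock g_sig_v, g_mu_a, g_sig_a, g_mu_t, g_sig_t, g_mu_w, g_sig_w;
  g_sig_v.init(G, 0, 0.3); g_mu_a.init(G, 0, 0.1); g_sig_a.init(G, 0, 0.3);
  g_mu_t.init(G, 0, 0.02); g_sig_t.init(G, 0, 0.3);
  g_mu_w.init(1, 0, 0.04); g_sig_w.init(1, 0, 0.3);

  Rng rng((std::uint64_t)seed);

  // cached per-cell log-likelihoods
  std::vector<double> cl((size_t)P * G, 0.0);
  auto cell_ll = [&](int p, int g, double vv, double aa, double tt,
                     double ww) -> double {
    const std::vector<int> &ix = idx[(size_t)p + (size_t)P * g];
    double s = 0.0;
    for (size_t k = 0; k < ix.size(); ++k) {
      int i = ix[k];
      double t = rt[i] - tt;
      if (!(t > 1e-6)) return -INFINITY;
      double l = wiener_lpdf_one(t, (int)upper[i], vv, aa, ww, tol, 0);
      if (l == -INFINITY) return -INFINITY;
      s += l;
    }
    return s;
  };
  for (int g = 0; g < G; ++g)
    for (int p = 0; p < P; ++p)
      cl[p + P * g] = cell_ll(p, g, v.val[p + P * g], a.val[p + P * g],
                              t0.val[p + P * g], w.val[p]);

  const int n_keep = (n_samples - burn_in) / thin;
  const int ncg = 6 * G + (bias ? 2 : 0) + 1;  // + deviance
  const int nci = 3 * P * G + (bias ? P : 0);
  NumericMatrix gdraw(n_keep, ncg), idraw(n_keep, nci);

  int stored = 0;
  for (int iter = 1; iter <= n_samples; ++iter) {
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
    bool adapting = iter <= burn_in;

    // --- group-level updates -------------------------------------------
    for (int g = 0; g < G; ++g) {
      // mu_v: conjugate normal given participant v's
      {
        double sum = 0.0;
        for (int p = 0; p < P; ++p) sum += v.val[p + P * g];
        double prec = 1.0 / (mu_v_sd * mu_v_sd) + P / (sig_v[g] * sig_v[g]);
        double mean = (mu_v_mean / (mu_v_sd * mu_v_sd) + sum / (sig_v[g] * sig_v[g])) / prec;
        mu_v[g] = mean + rng.norm() / std::sqrt(prec);
      }
      // sig_v: log-scale MH, half-normal prior
      {
        double cur = sig_v[g];
        double prop = cur * std::exp(g_sig_v.step[g] * rng.norm());
        g_sig_v.tries[g]++;
        if (prop > SIG_LO && prop < SIG_HI) {
          double lr = -prop * prop / (2 * ss_v * ss_v) + cur * cur / (2 * ss_v * ss_v)
                    + std::log(prop / cur);  // jacobian
          for (int p = 0; p < P; ++p)
            lr += ln_norm(v.val[p + P * g], mu_v[g], prop)
                - ln_norm(v.val[p + P * g], mu_v[g], cur);
          if (std::log(rng.unif()) < lr) { sig_v[g] = prop; g_sig_v.acc[g]++; }
        }
      }
      // mu_a: MH, truncated gamma prior
      {
        double cur = mu_a[g];
        double prop = cur + g_mu_a.step[g] * rng.norm();
        g_mu_a.tries[g]++;
        if (prop > a_lb && prop < A_HI) {
          double lr = (a_shape - 1.0) * std::log(prop / cur) - a_rate * (prop - cur);
          for (int p = 0; p < P; ++p)
            lr += ln_norm(a.val[p + P * g], prop, sig_a[g])
                - ln_norm(a.val[p + P * g], cur, sig_a[g]);
          if (std::log(rng.unif()) < lr) { mu_a[g] = prop; g_mu_a.acc[g]++; }
        }
      }
      // sig_a
      {
        double cur = sig_a[g];
        double prop = cur * std::exp(g_sig_a.step[g] * rng.norm());
        g_sig_a.tries[g]++;
        if (prop > SIG_LO && prop < SIG_HI) {
          double lr = -prop * prop / (2 * ss_a * ss_a) + cur * cur / (2 * ss_a * ss_a)
                    + std::log(prop / cur);
          for (int p = 0; p < P; ++p)
            lr += ln_norm(a.val[p + P * g], mu_a[g], prop)
                - ln_norm(a.val[p + P * g], mu_a[g], cur);
          if (std::log(rng.unif()) < lr) { sig_a[g] = prop; g_sig_a.acc[g]++; }
        }
      }
      // mu_t: MH, uniform prior on (tau_lb, tau_ub)
      {
        double cur = mu_t[g];
        double prop = cur + g_mu_t.step[g] * rng.norm();
        g_mu_t.tries[g]++;
        if (prop > tau_lb && prop < tau_ub) {
          double lr = 0.0;
          for (int p = 0; p < P; ++p)
            lr += ln_norm(t0.val[p + P * g], prop, sig_t[g])
                - ln_norm(t0.val[p + P * g], cur, sig_t[g]);
          if (std::log(rng.unif()) < lr) { mu_t[g] = prop; g_mu_t.acc[g]++; }
        }
      }
      // sig_t
      {
        double cur = sig_t[g];
        double prop = cur * std::exp(g_sig_t.step[g] * rng.norm());
        g_sig_t.tries[g]++;
        if (prop > SIG_LO && prop < SIG_HI) {
          double lr = -prop * prop / (2 * ss_t * ss_t) + cur * cur / (2 * ss_t * ss_t)
                    + std::log(prop / cur);
          for (int p = 0; p < P; ++p)
            lr += ln_norm(t0.val[p + P * g], mu_t[g], prop)
                - ln_norm(t0.val[p + P * g], mu_t[g], cur);
          if (std::log(rng.unif()) < lr) { sig_t[g] = prop; g_sig_t.acc[g]++; }
        }
      }
    }

    // --- participant-level updates (two sweeps per iteration to improve
    // mixing along the v/a/t0 ridge within each cell) -------------------
    for (int sweep = 0; sweep < 2; ++sweep)
    for (int g = 0; g < G; ++g) {
      for (int p = 0; p < P; ++p) {
        int k = p + P * g;
        // v
        {
          double cur = v.val[k];
          double prop = cur + v.step[k] * rng.norm();
          v.tries[k]++;
          if (prop > -V_B && prop < V_B) {
            double nll = cell_ll(p, g, prop, a.val[k], t0.val[k], w.val[p]);
            double lr = nll - cl[k] + ln_norm(prop, mu_v[g], sig_v[g])
                      - ln_norm(cur, mu_v[g], sig_v[g]);
            if (lr > 0 || std::log(rng.unif()) < lr) {
              v.val[k] = prop; cl[k] = nll; v.acc[k]++;
            }
          }
        }
        // a
        {
          double cur = a.val[k];
          double prop = cur + a.step[k] * rng.norm();
          a.tries[k]++;
          if (prop > A_LO && prop < A_HI) {
            double nll = cell_ll(p, g, v.val[k], prop, t0.val[k], w.val[p]);
            double lr = nll - cl[k] + ln_norm(prop, mu_a[g], sig_a[g])
                      - ln_norm(cur, mu_a[g], sig_a[g]);
            if (lr > 0 || std::log(rng.unif()) < lr) {
              a.val[k] = prop; cl[k] = nll; a.acc[k]++;
            }
          }
        }
        // t0
        {
          double cur = t0.val[k];
          double prop = cur + t0.step[k] * rng.norm();
          t0.tries[k]++;
          if (prop > T_LO && prop < T_HI) {
            double nll = cell_ll(p, g, v.val[k], a.val[k], prop, w.val[p]);
            double lr = nll - cl[k] + ln_norm(prop, mu_t[g], sig_t[g])
                      - ln_norm(cur, mu_t[g], sig_t[g]);
            if (lr > 0 || std::log(rng.unif()) < lr) {
              t0.val[k] = prop; cl[k] = nll; t0.acc[k]++;
            }
          }
        }
      }
    }

    // --- starting point (bias variant only) ----------------------------
    if (bias) {
      for (int p = 0; p < P; ++p) {
        double cur = w.val[p];
        double prop = cur + w.step[p] * rng.norm();
        w.tries[p]++;
        if (prop > W_LO && prop < W_HI) {
          std::vector<double> nll(G);
          double lr = ln_norm(prop, mu_w, sig_w) - ln_norm(cur, mu_w, sig_w);
          bool ok = true;
          for (int g = 0; g < G; ++g) {
            int k = p + P * g;
            nll[g] = cell_ll(p, g, v.val[k], a.val[k], t0.val[k], prop);
            if (nll[g] == -INFINITY) { ok = false; break; }
            lr += nll[g] - cl[k];
          }
          if (ok && (lr > 0 || std::log(rng.unif()) < lr)) {
            w.val[p] = prop; w.acc[p]++;
            for (int g = 0; g < G; ++g) cl[p + P * g] = nll[g];
          }
        }
      }
      // mu_w: MH with Beta(z_a, z_b) prior
      {
        double cur = mu_w;
        double prop = cur + g_mu_w.step[0] * rng.norm();
        g_mu_w.tries[0]++;
        if (prop > 0.02 && prop < 0.98) {
          double lr = (z_a - 1.0) * std::log(prop / cur)
                    + (z_b - 1.0) * std::log((1.0 - prop) / (1.0 - cur));
          for (int p = 0; p < P; ++p)
            lr += ln_norm(w.val[p], prop, sig_w) - ln_norm(w.val[p], cur, sig_w);
          if (std::log(rng.unif()) < lr) { mu_w = prop; g_mu_w.acc[0]++; }
        }
      }
      // sig_w
      {
        double cur = sig_w;
        double prop = cur * std::exp(g_sig_w.step[0] * rng.norm());
        g_sig_w.tries[0]++;
        if (prop > SIG_LO && prop < SIG_HI) {
          double lr = -prop * prop / (2 * ss_w * ss_w) + cur * cur / (2 * ss_w * ss_w)
                    + std::log(prop / cur);
          for (int p = 0; p < P; ++p)
            lr += ln_norm(w.val[p], mu_w, prop) - ln_norm(w.val[p], mu_w, cur);
          if (std::log(rng.unif()) < lr) { sig_w = prop; g_sig_w.acc[0]++; }
        }
      }
    }

    // --- adaptation (burn-in only) --------------------------------------
    if (adapting && iter % 25 == 0) {
      adapt(v.step, v.acc, v.tries); adapt(a.step, a.acc, a.tries);
      adapt(t0.step, t0.acc, t0.tries); adapt(w.step, w.acc, w.tries);
      adapt(g_sig_v.step, g_sig_v.acc, g_sig_v.tries);
      adapt(g_mu_a.step, g_mu_a.acc, g_mu_a.tries);
      adapt(g_sig_a.step, g_sig_a.acc, g_sig_a.tries);
      adapt(g_mu_t.step, g_mu_t.acc, g_mu_t.tries);
      adapt(g_sig_t.step, g_sig_t.acc, g_sig_t.tries);
      adapt(g_mu_w.step, g_mu_w.acc, g_mu_w.tries);
      adapt(g_sig_w.step, g_sig_w.acc, g_sig_w.tries);
    }

    // --- store -----------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0 && stored < n_keep) {
      int c = 0;
      for (int g = 0; g < G; ++g) gdraw(stored, c++) = mu_v[g];
      for (int g = 0; g < G; ++g) gdraw(stored, c++) = sig_v[g];
      for (int g = 0; g < G; ++g) gdraw(stored, c++) = mu_a[g];
      for (int g = 0; g < G; ++g) gdraw(stored, c++) = sig_a[g];
      for (int g = 0; g < G; ++g) gdraw(stored, c++) = mu_t[g];
      for (int g = 0; g < G; ++g) gdraw(stored, c++) = sig_t[g];
      if (bias) { gdraw(stored, c++) = mu_w; gdraw(stored, c++) = sig_w; }
      double dev = 0.0;
      for (size_t k = 0; k < cl.size(); ++k) dev += cl[k];
      gdraw(stored, c++) = -2.0 * dev;
      int ci = 0;
      for (int g = 0; g < G; ++g)
        for (int p = 0; p < P; ++p) idraw(stored, ci++) = v.val[p + P * g];
      for (int g = 0; g < G; ++g)
        for (int p = 0; p < P; ++p) idraw(stored, ci++) = a.val[p + P * g];
      for (int g = 0; g < G; ++g)
        for (int p = 0; p < P; ++p) idraw(stored, ci++) = t0.val[p + P * g];
      if (bias) for (int p = 0; p < P; ++p) idraw(stored, ci++) = w.val[p];
      stored++;
    }
  }

  auto rate = [](const ParBlock &b) {
    double s = 0.0; int n = 0;
    for (size_t i = 0; i < b.val.size(); ++i)
      if (b.tries[i] > 0) { s += (double)b.acc[i] / b.tries[i]; n++; }
    return n ? s / n : NA_REAL;
  };
  NumericVector acc_rates = NumericVector::create(
      _["v"] = rate(v), _["a"] = rate(a), _["t0"] = rate(t0),
      _["w"] = bias ? rate(w) : NA_REAL);

  return List::create(_["group"] = gdraw, _["indiv"] = idraw,
                      _["n_keep"] = n_keep, _["accept"] = acc_rates);
}

// Full-data log-likelihood at a parameter point (used for DIC's D(theta_bar)).
// [[Rcpp::export]]
double loglik_point_cpp(NumericVector rt, LogicalVector upper,
                        IntegerVector pid, IntegerVector cell, int P, int G,
                        NumericMatrix v, NumericMatrix a, NumericMatrix t0,
                        NumericVector w, double tol) {
  double s = 0.0;
  for (R_xlen_t i = 0; i < rt.size(); ++i) {
    int p = pid[i], g = cell[i];
    double t = rt[i] - t0(p, g);
    if (!(t > 1e-6)) return -INFINITY;
    double l = wiener_lpdf_one(t, (int)upper[i], v(p, g), a(p, g), w[p], tol, 0);
    if (l == -INFINITY) return -INFINITY;
    s += l;
  }
  return s;
}
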