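#ifndef VALDDM_WIENER_H
#define VALDDM_WIENER_H

#include <cmath>
#include <cstdint>
#include <random>

// Deterministic RNG: mt19937_64 raw output + explicit Box-Muller so that
// streams are bit-reproducible across platforms and compilers.
struct Rng {
  std::mt19937_64 g;
  bool has_spare;
  double spare;
  explicit Rng(std::uint64_t seed) : g(seed), has_spare(false), spare(0.0) {}
  double unif() {
    // open (0,1), 53-bit resolution
    return ((g() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// method: 0 = auto (Navarro-Fuss switch), 1 = small-time, 2 = large-time
double wiener_lpdf_one(double t, int upper, double v, double a, double w,
                       double tol, int method);
double wiener_pdf_one(double t, int upper, double v, double a, double w,
                      double tol, int method);
double prob_upper_one(double v, double a, double w);
// returns +1 upper, 0 lower, -1 unabsorbed by tmax; tdec set to decision time
int sim_one(Rng &rng, double v, double a, double w, double dt, double tmax,
            double &tdec);

#endif
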