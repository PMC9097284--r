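// Overdamped Langevin integrator (Euler-Maruyama) on a tabulated 1D landscape.
// Drift and noise amplitude are supplied pre-tabulated on a uniform grid and
// interpolated linearly; walls are handled by coordinate mirroring.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256** seeded from (seed, stream) so every replica gets an
// independent, reproducible stream regardless of R's RNG state.
struct Rng {
  uint64_t s[4];
  bool has_cache;
  double cache;
  Rng(uint64_t seed, uint64_t stream) : has_cache(false), cache(0.0) {
    uint64_t x = seed ^ (stream * 0xBF58476D1CE4E5B9ULL + 0x94D049BB133111EBULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // open (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // Marsaglia polar method with caching
    if (has_cache) { has_cache = false; return cache; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    cache = v * f;
    has_cache = true;
    return u * f;
  }
};

// shared-index interpolation of drift and noise amplitude
struct Tables {
  double g0, inv_ds;
  int n;
  const double *d, *a;
  Tables(double g0_, double ds_, const Rcpp::NumericVector &dv,
         const Rcpp::NumericVector &av)
      : g0(g0_), inv_ds(1.0 / ds_), n(dv.size()), d(REAL(dv)), a(REAL(av)) {}
  inline void at(double s, double &drift, double &amp) const {
    double u = (s - g0) * inv_ds;
    int i;
    double f;
    if (u <= 0.0) { i = 0; f = 0.0; }
    else if (u >= n - 1) { i = n - 2; f = 1.0; }
    else { i = (int)u; f = u - i; }
    drift = d[i] + f * (d[i + 1] - d[i]);
    amp = a[i] + f * (a[i + 1] - a[i]);
  }
};

struct Walls {
  double lo, hi, max_over;
  // mirror back into [lo, hi]; flag steps that overshoot pathologically
  inline double reflect(double s, bool &bad) const {
    if (s < lo) {
      if (lo - s > max_over) { bad = true; return lo; }
      s = 2.0 * lo - s;
    } else if (s > hi) {
      if (s - hi > max_over) { bad = true; return hi; }
      s = 2.0 * hi - s;
    }
    if (s < lo) s = lo;
    if (s > hi) s = hi;
    return s;
  }
};

}  // namespace

// Simulate one trajectory; returns positions thinned every `thin` steps,
// first element is s0.  drift and amp (= sqrt(2 D dt)) are tabulated on the
// uniform grid starting at g0 with spacing ds.
// [[Rcpp::export]]
NumericVector cpp_ld_simulate(double g0, double ds, NumericVector drift,
                              NumericVector amp, double lo, double hi,
                              double s0, double dt, double n_steps, int thin,
                              double seed, double stream) {
  Tables tb(g0, ds, drift, amp);
  Walls w{lo, hi, 0.25 * (hi - lo) + 4.0 * ds};
  Rng rng((uint64_t)seed, (uint64_t)stream);
  long long ns = (long long)n_steps;
  long long nout = ns / thin + 1;
  NumericVector out(nout);
  double s = s0;
  out[0] = s;
  bool bad = false;
  long long k = 0, j = 1;
  for (long long i = 1; i <= ns; ++i) {
    double dr, am;
      tb.at(s, dr, am);
      s += dr * dt + am * rng.norm();
    s = w.reflect(s, bad);
    if (bad) stop("Langevin step escaped the support; reduce dt");
    if (++k == thin) { out[j++] = s; k = 0; }
  }
  return out;
}

// Final positions of n_replicas independent trajectories after n_steps.
// [[Rcpp::export]]
NumericVector cpp_ld_endpoints(double g0, double ds, NumericVector drift,
                               NumericVector amp, double lo, double hi,
                               double s0, double dt, double n_steps,
                               double seed, double stream0, int n_replicas) {
  Tables tb(g0, ds, drift, amp);
  Walls w{lo, hi, 0.25 * (hi - lo) + 4.0 * ds};
  long long ns = (long long)n_steps;
  NumericVector out(n_replicas);
  for (int r = 0; r < n_replicas; ++r) {
    Rng rng((uint64_t)seed, (uint64_t)(stream0 + r));
    double s = s0;
    bool bad = false;
    for (long long i = 0; i < ns; ++i) {
      double dr, am;
      tb.at(s, dr, am);
      s += dr * dt + am * rng.norm();
      s = w.reflect(s, bad);
      if (bad) stop("Langevin step escaped the support; reduce dt");
    }
    out[r] = s;
  }
  return out;
}

// First-passage times to `target` for n_replicas trajectories started at
// s0; -1 where the horizon ran out.  A sign change of (s - target) is a
// certain crossing; for steps that stay on the starting side a Brownian
// bridge between the two endpoints decides whether the path touched the
// target within the step (removes the O(sqrt(dt)) detection bias of
// endpoint-only checks).
// [[Rcpp::export]]
NumericVector cpp_ld_first_passage(double g0, double ds, NumericVector drift,
                                   NumericVector amp, double lo, double hi,
                                   double s0, double target, double dt,
                                   double max_steps, double seed,
                                   double stream0, int n_replicas) {
  Tables tb(g0, ds, drift, amp);
  Walls w{lo, hi, 0.25 * (hi - lo) + 4.0 * ds};
  long long ms = (long long)max_steps;
  NumericVector out(n_replicas);
  double side0 = s0 - target;
  for (int r = 0; r < n_replicas; ++r) {
    if (side0 == 0.0) { out[r] = 0.0; continue; }
    Rng rng((uint64_t)seed, (uint64_t)(stream0 + r));
    double s = s0;
    double t = -1.0;
    bool bad = false;
    for (long long i = 1; i <= ms; ++i) {
      double prev = s;
      double dr, am;
      tb.at(s, dr, am);
      s += dr * dt + am * rng.norm();
      s = w.reflect(s, bad);
      if (bad) stop("Langevin step escaped the support; reduce dt");
      if ((s - target) * side0 <= 0.0) { t = i * dt; break; }
      // Brownian-bridge touch probability within the step
      double e = 2.0 * (prev - target) * (s - target) / (am * am);
      if (e < 30.0 && rng.unif() < std::exp(-e)) { t = i * dt; break; }
    }
    out[r] = t;
  }
  return out;
}

// Committor runs: +1 if the trajectory crosses `right` first, -1 if `left`
// first, 0 if uncommitted at the horizon.  Requires left < s0 < right.
// [[Rcpp::export]]
IntegerVector cpp_ld_committor(double g0, double ds, NumericVector drift,
                               NumericVector amp, double lo, double hi,
                               double s0, double left, double right, double dt,
                               double max_steps, double seed, double stream0,
                               int n_replicas) {
  Tables tb(g0, ds, drift, amp);
  Walls w{lo, hi, 0.25 * (hi - lo) + 4.0 * ds};
  long long ms = (long long)max_steps;
  IntegerVector out(n_replicas);
  for (int r = 0; r < n_replicas; ++r) {
    Rng rng((uint64_t)seed, (uint64_t)(stream0 + r));
    double s = s0;
    int res = 0;
    bool bad = false;
    for (long long i = 1; i <= ms; ++i) {
      double prev = s;
      double dr, am;
      tb.at(s, dr, am);
      s += dr * dt + am * rng.norm();
      s = w.reflect(s, bad);
      if (bad) stop("Langevin step escaped the support; reduce dt");
      if (s <= left) { res = -1; break; }
      if (s >= right) { res = 1; break; }
      // Brownian-bridge touch checks against both targets
      double el = 2.0 * (prev - left) * (s - left) / (am * am);
      if (el < 30.0 && rng.unif() < std::exp(-el)) { res = -1; break; }
      double er = 2.0 * (prev - right) * (s - right) / (am * am);
      if (er < 30.0 && rng.unif() < std::exp(-er)) { res = 1; break; }
    }
    out[r] = res;
  }
  return out;
}
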