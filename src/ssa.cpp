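#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// Counter-free splitmix64: deterministic across platforms, independent of
// R's RNG stream so trajectory reproducibility never depends on .Random.seed.
inline std::uint64_t splitmix64(std::uint64_t& state) {
  std::uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline double unif01(std::uint64_t& state) {
  // 53-bit mantissa draw in [0, 1)
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

}  // namespace

// Exact stochastic simulation (Gillespie direct method) of a mass-action
// reaction network. reactants/products are R x S stoichiometric matrices;
// the propensity of reaction r is rates[r] times the falling factorial of
// each reactant count, x_s (x_s - 1) ... (x_s - stoich + 1).
// The state is recorded at each grid time (state holding at that instant).
// [[Rcpp::export]]
NumericMatrix ssa_direct_cpp(NumericVector x0,
                             IntegerMatrix reactants,
                             IntegerMatrix products,
                             NumericVector rates,
                             NumericVector tgrid,
                             double seed,
                             double max_events) {
  const int S = x0.size();
  const int R = rates.size();
  const int T = tgrid.size();

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(R);
  NumericMatrix out(T, S);

  std::uint64_t rng =
      static_cast<std::uint64_t>(seed) * 0x2545F4914F6CDD1DULL + 0x9E3779B97F4A7C15ULL;
  for (int k = 0; k < 4; ++k) splitmix64(rng);  // decorrelate nearby seeds

  double t = 0.0;
  double events = 0.0;
  int gi = 0;

  for (;;) {
    double a0 = 0.0;
    for (int r = 0; r < R; ++r) {
      double ar = rates[r];
      for (int s = 0; s < S && ar > 0.0; ++s) {
        const int st = reactants(r, s);
        for (int k = 0; k < st; ++k) ar *= (x[s] - k > 0.0) ? (x[s] - k) : 0.0;
      }
      a[r] = ar;
      a0 += ar;
    }
    if (!std::isfinite(a0)) stop("propensity overflow: non-finite total propensity");

    const double tnext =
        (a0 > 0.0) ? t - std::log(1.0 - unif01(rng)) / a0 : R_PosInf;

    while (gi < T && tgrid[gi] < tnext) {
      for (int s = 0; s < S; ++s) out(gi, s) = x[s];
      ++gi;
    }
    if (gi >= T) break;

    double u = unif01(rng) * a0;
    int r = 0;
    double acc = a[0];
    while (r < R - 1 && u >= acc) acc += a[++r];
    for (int s = 0; s < S; ++s) x[s] += products(r, s) - reactants(r, s);
    t = tnext;
    if (++events > max_events) stop("SSA event budget exceeded (max_events)");
  }

  return out;
}
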