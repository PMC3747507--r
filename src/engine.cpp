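// Monte Carlo core for evolutionary games on one or two coupled lattices.
//
// The engine is deliberately self-contained: it carries its own counter-based
// PRNG (xoshiro256++ seeded through splitmix64) so that trajectories are
// bit-reproducible across platforms and independent of R's RNG state, and so
// that each lattice layer can consume a private stream (required for the
// exact alpha = 0 decoupling equivalence with isolated-lattice runs).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in {0, ..., n - 1}
  inline int below(int n) {
    int r = (int)(unif() * n);
    if (r >= n) r = n - 1;
    return r;
  }
};

// Deterministic sub-seed derivation: mixes an integer master seed with a
// text tag, returns an integer-valued double below 2^31 (safe as an R seed).
// [[Rcpp::export]]
double cpp_hash_seed(double seed, std::string tag) {
  uint64_t x = (uint64_t)(int64_t)seed;
  uint64_t h = splitmix64_next(x);
  for (size_t i = 0; i < tag.size(); ++i) {
    x = h ^ (uint64_t)(unsigned char)tag[i];
    h = splitmix64_next(x);
  }
  return (double)(h >> 33);
}

struct Engine {
  const int *neigh;   // n_sites x degree, column-major, 0-based site indices
  int *strat;         // n_sites x n_layers, 1 = C, 0 = D
  const int *dist;    // distinguished mask per layer (0/1)
  const int *partner; // 0-based partner site on the other layer
  int n, deg, n_layers;
  double pay[2][2];             // pay[s_x][s_y]
  double alpha, K, w_dist, w_ord, phi;
  int rule;                     // 0 fermi, 1 best-takes-over, 2 proportional
  std::vector<Xoshiro256> rng;  // one update stream per layer
  Xoshiro256 picker;            // layer-selection stream (pooled drawing)
  std::vector<long long> nC, nCd; // cooperator counts: total / distinguished

  Engine(const IntegerMatrix &neigh_, IntegerMatrix &strat_,
         const LogicalMatrix &dist_, const IntegerVector &partner_,
         double pay_T, double pay_R, double pay_P, double pay_S,
         double alpha_, int rule_,
         double K_, double w_dist_, double w_ord_, double phi_,
         const NumericVector &layer_seeds, double picker_seed)
      : neigh(neigh_.begin()), strat(strat_.begin()), dist(dist_.begin()),
        partner(partner_.begin()), picker((uint64_t)(int64_t)picker_seed) {
    n = neigh_.nrow();
    deg = neigh_.ncol();
    n_layers = strat_.ncol();
    pay[1][1] = pay_R; pay[1][0] = pay_S;
    pay[0][1] = pay_T; pay[0][0] = pay_P;
    alpha = alpha_; rule = rule_; K = K_;
    w_dist = w_dist_; w_ord = w_ord_; phi = phi_;
    for (int l = 0; l < n_layers; ++l)
      rng.emplace_back((uint64_t)(int64_t)layer_seeds[l]);
    nC.assign(n_layers, 0);
    nCd.assign(n_layers, 0);
    for (int l = 0; l < n_layers; ++l)
      for (int i = 0; i < n; ++i)
        if (S(i, l) == 1) {
          nC[l]++;
          if (D(i, l)) nCd[l]++;
        }
  }

  inline int S(int x, int l) const { return strat[(size_t)l * n + x]; }
  inline bool D(int x, int l) const {
    return dist[(size_t)l * n + x] != 0;
  }
  inline int NB(int x, int j) const { return neigh[(size_t)j * n + x]; }

  // nearest-neighbour payoff of site x on layer l
  inline double payoff(int x, int l) const {
    const double *row = pay[S(x, l)];
    const size_t base = (size_t)l * n;
    double p = 0.0;
    for (int j = 0; j < deg; ++j) p += row[strat[base + NB(x, j)]];
    return p;
  }

  // utility: own payoff, plus alpha times the partner's payoff on the other
  // layer for distinguished players (two-layer runs only)
  inline double utility(int x, int l) const {
    double u = payoff(x, l);
    if (n_layers > 1 && D(x, l)) u += alpha * payoff(partner[x], 1 - l);
    return u;
  }

  inline void set_strat(int x, int l, int s) {
    int &cur = strat[(size_t)l * n + x];
    if (cur == s) return;
    cur = s;
    const int d = (s == 1) ? 1 : -1;
    nC[l] += d;
    if (D(x, l)) nCd[l] += d;
  }

  inline double fermi_prob(double Ux, double Uy, double wy) const {
    double ex = (Ux - Uy) / K;
    if (ex > 700.0) ex = 700.0;
    if (ex < -700.0) ex = -700.0;
    return wy / (1.0 + std::exp(ex));
  }

  // one elementary update attempt on layer l
  void step(int l) {
    Xoshiro256 &r = rng[l];
    const int x = r.below(n);
    if (rule == 1) { // best-takes-over: argmax utility over closed nbhd
      double bestU = utility(x, l);
      int bestS = S(x, l);
      int nties = 1;
      for (int j = 0; j < deg; ++j) {
        const int y = NB(x, j);
        const double Uy = utility(y, l);
        if (Uy > bestU) {
          bestU = Uy;
          bestS = S(y, l);
          nties = 1;
        } else if (Uy == bestU) {
          // reservoir sampling: uniform tie-break over all maximizers
          nties++;
          if (r.unif() * nties < 1.0) bestS = S(y, l);
        }
      }
      set_strat(x, l, bestS);
      return;
    }
    const int y = NB(x, r.below(deg));
    const double Ux = utility(x, l);
    const double Uy = utility(y, l);
    double p;
    if (rule == 0) {
      const double wy = D(y, l) ? w_dist : w_ord;
      p = fermi_prob(Ux, Uy, wy);
    } else { // proportional imitation
      p = (Uy > Ux) ? (Uy - Ux) / phi : 0.0;
    }
    if (r.unif() < p) set_strat(x, l, S(y, l));
  }

  bool all_homogeneous() const {
    for (int l = 0; l < n_layers; ++l)
      if (nC[l] != 0 && nC[l] != (long long)n) return false;
    return true;
  }
};

// Run the asynchronous dynamics.
//
// interleave: 0 = pooled (focal layer drawn per elementary step from the
//             picker stream, uniform over layers), 1 = alternating (layers
//             visited round-robin; with separate per-layer streams this makes
//             each layer's draw sequence identical to an isolated run).
// n_steps_override >= 0 runs exactly that many elementary steps (no
// per-MCS recording); otherwise n_mcs full Monte Carlo steps of
// n_layers * n_sites elementary steps each are run.
// [[Rcpp::export]]
List cpp_run_engine(const IntegerMatrix &neigh, const IntegerMatrix &strat_in,
                    const LogicalMatrix &dist, const IntegerVector &partner,
                    double T, double R, double P, double S, double alpha,
                    int rule, double K, double w_dist, double w_ord,
                    double phi, int n_mcs, double n_steps_override,
                    int interleave, NumericVector layer_seeds,
                    double picker_seed, bool record) {
  IntegerMatrix strat = clone(strat_in);
  Engine eng(neigh, strat, dist, partner, T, R, P, S, alpha, rule, K, w_dist,
             w_ord, phi, layer_seeds, picker_seed);
  const int n_layers = eng.n_layers;
  const long long steps_per_mcs = (long long)n_layers * eng.n;

  bool absorbed = eng.all_homogeneous();
  int absorbed_at = absorbed ? 0 : -1;

  if (n_steps_override >= 0) {
    const long long total = (long long)n_steps_override;
    for (long long t = 0; t < total; ++t) {
      const int l = (interleave == 0) ? eng.picker.below(n_layers)
                                      : (int)(t % n_layers);
      eng.step(l);
    }
    absorbed = eng.all_homogeneous();
    return List::create(_["strat"] = strat, _["records"] = R_NilValue,
                        _["absorbed"] = absorbed,
                        _["absorbed_at"] = absorbed ? 0 : -1);
  }

  IntegerMatrix records;
  if (record) records = IntegerMatrix(n_mcs + 1, 2 * n_layers);
  auto record_row = [&](int row) {
    for (int l = 0; l < n_layers; ++l) {
      records(row, 2 * l) = (int)eng.nC[l];
      records(row, 2 * l + 1) = (int)eng.nCd[l];
    }
  };
  if (record) record_row(0);

  long long step_idx = 0;
  for (int m = 1; m <= n_mcs; ++m) {
    if (!absorbed) {
      for (long long t = 0; t < steps_per_mcs; ++t, ++step_idx) {
        const int l = (interleave == 0) ? eng.picker.below(n_layers)
                                        : (int)(step_idx % n_layers);
        eng.step(l);
      }
      if (eng.all_homogeneous()) {
        absorbed = true;
        absorbed_at = m;
      }
    }
    if (record) record_row(m);
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["strat"] = strat,
                      _["records"] = record ? (SEXP)records : R_NilValue,
                      _["absorbed"] = absorbed,
                      _["absorbed_at"] = absorbed_at);
}
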