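// Two-deme structured-coalescent sampler with piecewise-constant migration
// and piecewise-exponential population size, used both to build expected
// joint site frequency spectra and as the engine behind composite-likelihood
// fitting (where speed matters: one likelihood evaluation draws thousands of
// genealogies).
//
// Epochs are supplied from R as a matrix, one row per epoch looking
// backwards in time, columns:
//   0 t_start  1 t_end  2 two_demes (1/0)  3 m (per-lineage, per-generation)
//   4 N1 (diploid, at t_start)  5 g1 (backwards exponential rate)
//   6 N2  7 g2
// Within an epoch the diploid size of deme d at time t is
// N_d(t) = N_d * exp(g_d * (t - t_start)); pairwise coalescence rate is
// 1/(2 N_d(t)). In a single-deme epoch every lineage sits in deme 0 and
// N1/g1 describe the ancestral population.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <algorithm>
#include <map>
#include <vector>

namespace {

// splitmix64: scrambles (seed ^ replicate) into well-separated streams.
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) { x = splitmix64(x); s[i] = x; }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  inline double u01() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rexp() { return -std::log(u01()); }
};

struct Lineage {
  int deme;
  int i;     // descendants in sample 1
  int j;     // descendants in sample 2
  double born;  // time its current branch segment started accruing
};

// Waiting time to a coalescence among k lineages when the hazard is
// A * exp(-g s) with A = k(k-1)/2 / (2 N_now); returns +inf if the event
// never happens (possible when g > 0, i.e. the population grows backwards).
inline double coal_wait(double k, double n_now, double g, double u) {
  if (k < 2.0 || n_now <= 0.0) return INFINITY;
  double A = 0.5 * k * (k - 1.0) / (2.0 * n_now);
  if (g == 0.0) return u / A;
  double z = 1.0 - g * u / A;
  if (z <= 0.0) return INFINITY;
  return -std::log(z) / g;
}

}  // namespace

// Expected branch lengths contributed by the final constant-size
// single-deme epoch, computed analytically instead of simulated
// (Rao-Blackwellization). For j exchangeable lineages entering a
// constant-size coalescent of diploid size N, the expected total length of
// branches subtending exactly s of them is 4N/s, and each of the C(j, s)
// subsets is equally likely, so a specific subset carries (4N/s)/C(j, s).
// The subset-sum distribution over descendant configurations (a, b) is
// accumulated by polynomial DP over lineages. Removes all Monte Carlo
// variance from the (deepest, highest-variance) ancestral phase.
static void analytic_ancestral_tail(const std::vector<Lineage> &lin,
                                    double n_anc, int nr, int nc,
                                    std::vector<double> &tally,
                                    double &extra_tmrca,
                                    std::vector<double> &dp) {
  const int j = (int)lin.size();
  const int ncell = nr * nc;
  // dp[s * ncell + cell]: number of size-s subsets with summed config (a, b)
  std::fill(dp.begin(), dp.begin() + (size_t)(j + 1) * ncell, 0.0);
  dp[0] = 1.0;
  for (int l = 0; l < j; ++l) {
    const int off = lin[l].i * nc + lin[l].j;
    for (int s = std::min(l, j - 1); s >= 0; --s) {
      const double *src = dp.data() + (size_t)s * ncell;
      double *dst = dp.data() + (size_t)(s + 1) * ncell;
      for (int c = ncell - 1 - off; c >= 0; --c) {
        if (src[c] != 0.0) dst[c + off] += src[c];
      }
    }
  }
  double choose = (double)j;  // C(j, s), updated incrementally
  for (int s = 1; s <= j - 1; ++s) {
    const double w = (4.0 * n_anc / s) / choose;
    const double *row = dp.data() + (size_t)s * ncell;
    for (int c = 0; c < ncell; ++c) {
      if (row[c] != 0.0) tally[c] += w * row[c];
    }
    choose *= (double)(j - s) / (double)(s + 1);
  }
  extra_tmrca = 4.0 * n_anc * (1.0 - 1.0 / j);
}

// Cached analytic-tail results, keyed by the sorted multiset of lineage
// configurations entering the ancestral epoch (identical multisets give
// identical expected contributions, and multisets repeat heavily across
// replicates).
struct TailResult {
  std::vector<std::pair<int, double>> cells;
  double extra_tmrca;
};

struct Epoch {
  double t_start, t_end, m, n1, g1, n2, g2;
  bool two;
};

// Returns per-cell mean and variance of branch length subtending each
// descendant configuration (i, j), plus TMRCA and total-length summaries.
// When analytic_tail is true and at most 30 lineages survive to the final
// constant-size single-deme epoch, that epoch's contribution is added as an
// exact expectation rather than simulated.
// [[Rcpp::export(name = ".sim_branch_tally")]]
Rcpp::List sim_branch_tally(Rcpp::NumericMatrix epochs, int k1, int k2,
                            int n_reps, double seed,
                            bool analytic_tail = false) {
  if (k1 < 0 || k2 < 0 || k1 + k2 < 2)
    Rcpp::stop("need at least two sampled chromosomes in total");
  if (n_reps < 1) Rcpp::stop("n_reps must be at least 1");
  const int nr = k1 + 1, nc = k2 + 1;
  const int ne = epochs.nrow();
  for (int e = 0; e < ne; ++e) {
    if (epochs(e, 3) < 0 || epochs(e, 3) >= 1.0)
      Rcpp::stop("migration rate must lie in [0, 1)");
    if (epochs(e, 4) <= 0 || (epochs(e, 2) > 0.5 && epochs(e, 6) <= 0))
      Rcpp::stop("population sizes must be positive");
  }

  std::vector<double> mean_t(nr * nc, 0.0), m2_t(nr * nc, 0.0);
  double mean_tmrca = 0.0, m2_tmrca = 0.0;
  double mean_len = 0.0, m2_len = 0.0;
  std::vector<double> tally(nr * nc);
  std::vector<double> dp_buf((size_t)(std::min(k1 + k2, 30) + 1) * nr * nc);
  std::vector<double> tail_scratch(nr * nc);
  std::map<std::vector<int>, TailResult> tail_cache;
  std::vector<int> tail_key;
  std::vector<Lineage> lin;
  lin.reserve(k1 + k2);
  std::vector<Epoch> ep(ne);
  for (int i = 0; i < ne; ++i) {
    ep[i] = {epochs(i, 0), epochs(i, 1), epochs(i, 3), epochs(i, 4),
             epochs(i, 5), epochs(i, 6), epochs(i, 7), epochs(i, 2) > 0.5};
  }

  // scramble the user seed so small integers give unrelated stream sets
  const uint64_t base = splitmix64((uint64_t)llround(seed));

  for (int rep = 0; rep < n_reps; ++rep) {
    Xoshiro rng(base ^ (uint64_t)rep);
    std::fill(tally.begin(), tally.end(), 0.0);
    lin.clear();
    for (int a = 0; a < k1; ++a) lin.push_back({0, 1, 0, 0.0});
    for (int b = 0; b < k2; ++b) lin.push_back({1, 0, 1, 0.0});

    double t = 0.0;
    int e = 0;
    double tmrca = 0.0;
    int c1 = k1, c2 = k2;  // lineages per deme, maintained incrementally
    // Branch lengths are accounted lazily: a lineage's segment is added to
    // the tally only when its descendant configuration changes (at a
    // coalescence) or at the end, since migrations and epoch changes leave
    // configurations untouched. Migration events are then O(1).
    while (lin.size() > 1) {
      while (e < ne - 1 && t >= ep[e].t_end) ++e;
      if (analytic_tail && e == ne - 1 && !ep[e].two &&
          ep[e].g1 == 0.0 && (int)lin.size() <= 30) {
        for (auto &l : lin) {
          tally[l.i * nc + l.j] += t - l.born;
          l.born = t;
        }
        tail_key.clear();
        for (auto &l : lin) tail_key.push_back(l.i * nc + l.j);
        std::sort(tail_key.begin(), tail_key.end());
        auto hit = tail_cache.find(tail_key);
        if (hit == tail_cache.end()) {
          std::fill(tail_scratch.begin(), tail_scratch.end(), 0.0);
          double extra = 0.0;
          analytic_ancestral_tail(lin, ep[e].n1, nr, nc, tail_scratch,
                                  extra, dp_buf);
          TailResult res;
          res.extra_tmrca = extra;
          for (int c = 0; c < nr * nc; ++c) {
            if (tail_scratch[c] != 0.0) res.cells.push_back({c, tail_scratch[c]});
          }
          hit = tail_cache.emplace(tail_key, std::move(res)).first;
        }
        for (auto &cv : hit->second.cells) tally[cv.first] += cv.second;
        tmrca = t + hit->second.extra_tmrca;
        lin.resize(1);
        break;
      }
      const bool two = ep[e].two;
      const double t0 = ep[e].t_start, t1 = ep[e].t_end;
      const double mig = two ? ep[e].m : 0.0;
      if (!two && c2 > 0) {
        for (auto &l : lin) l.deme = 0;
        c1 = (int)lin.size();
        c2 = 0;
      }
      const double g1 = ep[e].g1, g2 = ep[e].g2;
      const double n1_now = (g1 == 0.0) ? ep[e].n1
                                        : ep[e].n1 * std::exp(g1 * (t - t0));
      const double n2_now = !two ? 1.0
                            : (g2 == 0.0) ? ep[e].n2
                                          : ep[e].n2 * std::exp(g2 * (t - t0));
      const double w1 = coal_wait(c1, n1_now, g1, rng.rexp());
      const double w2 = two ? coal_wait(c2, n2_now, g2, rng.rexp()) : INFINITY;
      const double wm = (mig > 0.0 && two)
                            ? rng.rexp() / (mig * (double)lin.size())
                            : INFINITY;
      double w = std::min(w1, std::min(w2, wm));
      const double cap = t1 - t;
      t += std::min(w, cap);
      if (w >= cap) continue;  // crossed an epoch boundary: recompute rates
      if (w == wm) {
        int pick = (int)(rng.u01() * lin.size());
        if (pick >= (int)lin.size()) pick = (int)lin.size() - 1;
        if (lin[pick].deme == 0) { --c1; ++c2; } else { ++c1; --c2; }
        lin[pick].deme = 1 - lin[pick].deme;
      } else {
        const int deme = (w == w1) ? 0 : 1;
        const int kd = (deme == 0) ? c1 : c2;
        // choose an unordered pair uniformly within the deme
        int a = (int)(rng.u01() * kd);
        int b = (int)(rng.u01() * (kd - 1));
        if (a >= kd) a = kd - 1;
        if (b >= kd - 1) b = kd - 2;
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (int idx = 0; idx < (int)lin.size(); ++idx) {
          if (lin[idx].deme == deme) {
            if (seen == a) ia = idx;
            if (seen == b) ib = idx;
            ++seen;
          }
        }
        tally[lin[ia].i * nc + lin[ia].j] += t - lin[ia].born;
        tally[lin[ib].i * nc + lin[ib].j] += t - lin[ib].born;
        lin[ia].i += lin[ib].i;
        lin[ia].j += lin[ib].j;
        lin[ia].born = t;
        lin[ib] = lin.back();
        lin.pop_back();
        if (deme == 0) --c1; else --c2;
        if (lin.size() == 1) tmrca = t;
      }
    }

    double len = 0.0;
    for (int c = 0; c < nr * nc; ++c) len += tally[c];
    const double nrep = rep + 1.0;
    for (int c = 0; c < nr * nc; ++c) {
      const double d = tally[c] - mean_t[c];
      mean_t[c] += d / nrep;
      m2_t[c] += d * (tally[c] - mean_t[c]);
    }
    double d = tmrca - mean_tmrca;
    mean_tmrca += d / nrep;
    m2_tmrca += d * (tmrca - mean_tmrca);
    d = len - mean_len;
    mean_len += d / nrep;
    m2_len += d * (len - mean_len);
  }

  Rcpp::NumericMatrix mean_out(nr, nc), var_out(nr, nc);
  const double denom = (n_reps > 1) ? (n_reps - 1.0) : 1.0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      mean_out(i, j) = mean_t[i * nc + j];
      var_out(i, j) = (n_reps > 1) ? m2_t[i * nc + j] / denom : 0.0;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("mean_tally") = mean_out,
      Rcpp::Named("var_tally") = var_out,
      Rcpp::Named("mean_tmrca") = mean_tmrca,
      Rcpp::Named("var_tmrca") = (n_reps > 1) ? m2_tmrca / denom : 0.0,
      Rcpp::Named("mean_total_length") = mean_len,
      Rcpp::Named("var_total_length") = (n_reps > 1) ? m2_len / denom : 0.0,
      Rcpp::Named("n_reps") = n_reps);
}
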