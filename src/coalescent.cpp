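// Structured coalescent for two demes with exponential size change and
// asymmetric migration, in the parameterisation used for SFS inference:
// sizes in units of N_A, time in units of 2*N_A generations, coalescence
// rate choose(k,2)/nu_deme(t), backward migration rate M/2 per lineage.
// Event times are sampled by thinning against an upper bound on the total
// hazard over the remaining pre-split interval.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(uint64_t seed) : eng(seed) {}
  double u() {
    double x;
    do { x = unif(eng); } while (x <= 0.0 || x >= 1.0);
    return x;
  }
  double rexp(double rate) { return -std::log(u()) / rate; }
  int ri(int n) { return (int)(u() * n) % n; }  // 0..n-1
};

// Deme size at time t back from the present, t in [0, T].
// With growth: nu(0) = N_now, nu(T) = s_split, exponential in between.
inline double deme_size(double N_now, double s_split, double t, double T,
                        bool growth) {
  if (!growth || T <= 0.0) return N_now;
  return N_now * std::pow(s_split / N_now, t / T);
}

struct Lineage {
  int d1, d2;        // present-day descendants in species 1 / species 2
  int deme;          // 0 or 1
  uint64_t mask;     // descendant leaves as a bitmask (leaf order: sp1, sp2)
  double len;        // accumulated branch length since lineage birth
  int node;          // node id (for genealogy export)
};

struct SimOut {
  std::vector<double> blen;      // finalized branch lengths
  std::vector<uint64_t> bmask;   // finalized branch masks
  std::vector<int> bd1, bd2;     // descendant counts per finalized branch
  // genealogy export (merge records)
  std::vector<int> parent;       // parent node id per node (root = -1)
  std::vector<double> ntime;     // node time (leaves at 0)
  double tmrca;
};

// One genealogy for n1 + n2 sampled haploid lineages.  When `record`
// is true, per-branch masks and merge records are kept (synthetic data
// and tree export); the SFS-only path skips them.
void simulate_one(double N1, double N2, double s, double T, double m1,
                  double m2, bool growth, int n1, int n2, Rng& rng,
                  NumericMatrix* sfs_acc, bool record, SimOut* out) {
  const int n = n1 + n2;
  std::vector<Lineage> L(n);
  for (int i = 0; i < n; ++i) {
    bool sp1 = i < n1;
    L[i].d1 = sp1 ? 1 : 0;
    L[i].d2 = sp1 ? 0 : 1;
    L[i].deme = sp1 ? 0 : 1;
    L[i].mask = (uint64_t)1 << i;
    L[i].len = 0.0;
    L[i].node = i;
  }
  int next_node = n;
  if (record) {
    out->parent.assign(2 * n - 1, -1);
    out->ntime.assign(2 * n - 1, 0.0);
  }
  double t = 0.0;

  auto add_time = [&](double dt) {
    if (dt <= 0.0) return;
    if (sfs_acc) {
      for (size_t i = 0; i < L.size(); ++i)
        (*sfs_acc)(L[i].d1, L[i].d2) += dt;
    }
    if (record)
      for (size_t i = 0; i < L.size(); ++i) L[i].len += dt;
  };
  auto coalesce = [&](int a, int b, double when) {
    if (record) {
      out->blen.push_back(L[a].len);
      out->bmask.push_back(L[a].mask);
      out->bd1.push_back(L[a].d1);
      out->bd2.push_back(L[a].d2);
      out->blen.push_back(L[b].len);
      out->bmask.push_back(L[b].mask);
      out->bd1.push_back(L[b].d1);
      out->bd2.push_back(L[b].d2);
      out->parent[L[a].node] = next_node;
      out->parent[L[b].node] = next_node;
      out->ntime[next_node] = when;
    }
    L[a].d1 += L[b].d1;
    L[a].d2 += L[b].d2;
    L[a].mask |= L[b].mask;
    L[a].len = 0.0;
    L[a].node = next_node++;
    L.erase(L.begin() + b);
  };
  auto pick_pair_in_deme = [&](int deme, int k, int* a, int* b) {
    int i = rng.ri(k), j = rng.ri(k - 1);
    if (j >= i) ++j;
    if (i > j) std::swap(i, j);
    int seen = -1;
    *a = -1; *b = -1;
    for (size_t idx = 0; idx < L.size(); ++idx) {
      if (L[idx].deme != deme) continue;
      ++seen;
      if (seen == i) *a = (int)idx;
      else if (seen == j) { *b = (int)idx; break; }
    }
  };

  // phase 1: two demes, t in [0, T].  The thinning majorant is refreshed
  // on a short horizon so exponentially shrinking demes do not force a
  // hopelessly loose global bound (sizes change by at most e^0.5 within
  // one horizon).
  const double g1 = (growth && T > 0) ? std::log(s / N1) / T : 0.0;
  const double g2 = (growth && T > 0) ? std::log((1.0 - s) / N2) / T : 0.0;
  const double gmax = std::max(std::fabs(g1), std::fabs(g2));
  const double horizon = gmax > 0 ? 0.5 / gmax : T;
  while (t < T && L.size() > 1) {
    int k1 = 0;
    for (auto& x : L) if (x.deme == 0) ++k1;
    int k2 = (int)L.size() - k1;
    double t_bound = std::min(T, t + horizon);
    // monotone exponential trajectories: min on [t, t_bound] at an endpoint
    double nu1_min = std::min(deme_size(N1, s, t, T, growth),
                              deme_size(N1, s, t_bound, T, growth));
    double nu2_min = std::min(deme_size(N2, 1.0 - s, t, T, growth),
                              deme_size(N2, 1.0 - s, t_bound, T, growth));
    double lam_max = 0.5 * k1 * (k1 - 1) / nu1_min + 0.5 * k2 * (k2 - 1) / nu2_min
                   + k1 * m1 / 2.0 + k2 * m2 / 2.0;
    if (lam_max <= 0.0) { add_time(T - t); t = T; break; }
    double dt = rng.rexp(lam_max);
    if (t + dt >= t_bound) {           // no event before the horizon
      add_time(t_bound - t);
      t = t_bound;
      continue;
    }
    add_time(dt);
    t += dt;
    double r_c1 = 0.5 * k1 * (k1 - 1) / deme_size(N1, s, t, T, growth);
    double r_c2 = 0.5 * k2 * (k2 - 1) / deme_size(N2, 1.0 - s, t, T, growth);
    double r_m1 = k1 * m1 / 2.0;
    double r_m2 = k2 * m2 / 2.0;
    double u = rng.u() * lam_max;
    if (u < r_c1) {
      int a, b; pick_pair_in_deme(0, k1, &a, &b);
      coalesce(a, b, t);
    } else if (u < r_c1 + r_c2) {
      int a, b; pick_pair_in_deme(1, k2, &a, &b);
      coalesce(a, b, t);
    } else if (u < r_c1 + r_c2 + r_m1) {
      int i = rng.ri(k1), seen = -1;
      for (auto& x : L) { if (x.deme == 0 && ++seen == i) { x.deme = 1; break; } }
    } else if (u < r_c1 + r_c2 + r_m1 + r_m2) {
      int i = rng.ri(k2), seen = -1;
      for (auto& x : L) { if (x.deme == 1 && ++seen == i) { x.deme = 0; break; } }
    }  // else: thinning rejection
  }

  // phase 2: ancestral panmictic deme of size 1 (N_A units)
  for (auto& x : L) x.deme = 0;
  while (L.size() > 1) {
    int k = (int)L.size();
    double rate = 0.5 * k * (k - 1);
    double dt = rng.rexp(rate);
    add_time(dt);
    t += dt;
    int i = rng.ri(k), j = rng.ri(k - 1);
    if (j >= i) ++j;
    if (i > j) std::swap(i, j);
    coalesce(i, j, t);
  }
  if (record) out->tmrca = t;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_expected_sfs(double N1, double N2, double s, double T,
                               double m1, double m2, bool growth,
                               int n1, int n2, int nreps, double seed) {
  if (N1 <= 0 || N2 <= 0) stop("population sizes must be positive");
  if (T < 0) stop("split time must be non-negative");
  NumericMatrix acc(n1 + 1, n2 + 1);
  Rng rng((uint64_t)seed);
  for (int r = 0; r < nreps; ++r)
    simulate_one(N1, N2, s, T, m1, m2, growth, n1, n2, rng, &acc, false, nullptr);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) acc(i, j) /= nreps;
  acc(0, 0) = 0.0;
  acc(n1, n2) = 0.0;
  return acc;
}

// One genealogy with per-branch descendant masks, for mutation dropping
// and tree export.  Leaves 1..n1 are species 1, n1+1..n1+n2 species 2
// (1-based in the returned merge records).
// [[Rcpp::export]]
List cpp_simulate_genealogy(double N1, double N2, double s, double T,
                            double m1, double m2, bool growth,
                            int n1, int n2, double seed) {
  if (n1 + n2 > 62) stop("at most 62 haploid samples supported");
  if (N1 <= 0 || N2 <= 0) stop("population sizes must be positive");
  Rng rng((uint64_t)seed);
  SimOut out;
  simulate_one(N1, N2, s, T, m1, m2, growth, n1, n2, rng, nullptr, true, &out);
  int nb = (int)out.blen.size();
  NumericVector blen(nb), bmask(nb);
  IntegerVector bd1(nb), bd2(nb);
  for (int i = 0; i < nb; ++i) {
    blen[i] = out.blen[i];
    bmask[i] = (double)out.bmask[i];  // exact: < 2^53 for <= 52 leaves
    bd1[i] = out.bd1[i];
    bd2[i] = out.bd2[i];
  }
  IntegerVector parent(out.parent.begin(), out.parent.end());
  NumericVector ntime(out.ntime.begin(), out.ntime.end());
  return List::create(_["branch_length"] = blen, _["branch_mask"] = bmask,
                      _["branch_d1"] = bd1, _["branch_d2"] = bd2,
                      _["parent"] = parent + 1, _["node_time"] = ntime,
                      _["tmrca"] = out.tmrca);
}
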