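// Event-driven structured coalescent for two daughter populations descended
// from a split, with epoch-dependent asymmetric migration (SI/IM/AM/SC family).
//
// Time runs backward in units of 2*N_anc generations. Population sizes nu1,
// nu2 are relative to the ancestral size; scaled migration rates m12, m21 are
// 2*N_anc times the per-generation backward migration fractions (a lineage
// currently in population 1 jumps to population 2 at rate m12, matching the
// usual forward convention of m12 = migration into population 1 from
// population 2).
//
// Randomness: a private splitmix64 stream, so calls never perturb R's RNG and
// every result is reproducible from an integer seed. Exponential waiting
// budgets are carried across epoch boundaries (the budget is spent against the
// integrated total rate), and events are selected by a single uniform against
// cumulative rates. Zero-rate event types therefore consume no randomness:
// models whose rate functions coincide (IM with m=0 vs SI; AM with Ta=0 vs
// IM; SC with Tsc=Ts vs IM) produce identical event streams from the same
// seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo() { return -std::log(unif()); }
  int poisson(double mean) {
    if (mean <= 0.0) return 0;
    if (mean > 5000.0) {  // normal approximation for very long trees
      double u1 = unif(), u2 = unif();
      double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
      double x = mean + std::sqrt(mean) * z;
      return x < 0 ? 0 : (int)std::floor(x + 0.5);
    }
    double L = std::exp(-mean), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

struct Lineage {
  int node;      // tree node id (tips first)
  int c1, c2;    // descendant tip counts in pop1 / pop2
  double birth;  // backward time the lineage came into existence
};

struct Tree {
  std::vector<int> parent;
  std::vector<double> time;
};

// model codes: 0 = SI, 1 = IM, 2 = AM, 3 = SC
inline bool mig_active(int model, double t, double Ts, double Tc) {
  if (t >= Ts) return false;
  switch (model) {
    case 0: return false;
    case 1: return true;
    case 2: return t >= Tc;  // ancient flow: active between Tc and the split
    case 3: return t < Tc;   // secondary contact: active from present to Tc
  }
  return false;
}

// One genealogy of n1h + n2h sampled chromosomes. Accumulates branch lengths
// by joint descendant configuration into jsfs (if non-null) and/or records
// the full topology into tree (if non-null).
void sim_genealogy(XRng& rng, int model, double nu1, double nu2, double Ts,
                   double Tc, double m12, double m21, int n1h, int n2h,
                   double* jsfs /* (n1h+1) x (n2h+1), column-major */,
                   Tree* tree) {
  const int ntips = n1h + n2h;
  static thread_local std::vector<Lineage> deme[2];
  deme[0].clear(); deme[1].clear();
  deme[0].reserve(2 * ntips); deme[1].reserve(2 * ntips);
  for (int i = 0; i < n1h; ++i) deme[0].push_back({i, 1, 0, 0.0});
  for (int i = 0; i < n2h; ++i) deme[1].push_back({n1h + i, 0, 1, 0.0});
  if (tree) {
    tree->parent.assign(2 * ntips - 1, -1);
    tree->time.assign(2 * ntips - 1, 0.0);
  }
  double t = 0.0;
  int nextnode = ntips;
  bool merged = (Ts <= 0.0);
  if (merged) {
    for (auto& l : deme[1]) deme[0].push_back(l);
    deme[1].clear();
  }

  while ((int)(deme[0].size() + deme[1].size()) > 1) {
    double E = rng.expo();
    double rate[4];  // coal pop1, coal pop2, mig 1->2, mig 2->1
    double R;
    for (;;) {
      double j0 = (double)deme[0].size(), j1 = (double)deme[1].size();
      if (merged) {
        rate[0] = 0.5 * j0 * (j0 - 1.0);
        rate[1] = rate[2] = rate[3] = 0.0;
      } else {
        bool mig = mig_active(model, t, Ts, Tc);
        rate[0] = 0.5 * j0 * (j0 - 1.0) / nu1;
        rate[1] = 0.5 * j1 * (j1 - 1.0) / nu2;
        rate[2] = mig ? j0 * m12 : 0.0;
        rate[3] = mig ? j1 * m21 : 0.0;
      }
      R = rate[0] + rate[1] + rate[2] + rate[3];
      double bnd = R_PosInf;
      if (!merged) {
        bnd = Ts;
        if ((model == 2 || model == 3) && t < Tc && Tc < Ts) bnd = Tc;
      }
      if (R > 0.0 && t + E / R <= bnd) {
        t += E / R;
        break;
      }
      // spend the waiting budget up to the boundary, then change epoch
      E -= R * (bnd - t);
      t = bnd;
      if (t >= Ts && !merged) {
        merged = true;
        for (auto& l : deme[1]) deme[0].push_back(l);
        deme[1].clear();
      }
    }

    double u = rng.unif() * R;
    int ev = 0;
    while (ev < 3 && u >= rate[ev]) { u -= rate[ev]; ++ev; }
    if (ev <= 1) {  // coalescence in deme ev
      std::vector<Lineage>& d = deme[ev];
      int j = (int)d.size();
      int a = (int)(rng.unif() * j); if (a >= j) a = j - 1;
      int b = (int)(rng.unif() * (j - 1)); if (b >= j - 1) b = j - 2;
      if (b >= a) ++b;
      Lineage pa = {nextnode, d[a].c1 + d[b].c1, d[a].c2 + d[b].c2, t};
      if (jsfs) {
        jsfs[d[a].c1 + (n1h + 1) * d[a].c2] += t - d[a].birth;
        jsfs[d[b].c1 + (n1h + 1) * d[b].c2] += t - d[b].birth;
      }
      if (tree) {
        tree->parent[d[a].node] = nextnode;
        tree->parent[d[b].node] = nextnode;
        tree->time[nextnode] = t;
      }
      ++nextnode;
      // unordered removal: replace with the last element
      if (a > b) std::swap(a, b);
      d[b] = d.back(); d.pop_back();
      d[a] = d.back(); d.pop_back();
      d.push_back(pa);
    } else {  // migration out of deme (ev - 2)
      int from = ev - 2, to = 1 - from;
      int j = (int)deme[from].size();
      int a = (int)(rng.unif() * j); if (a >= j) a = j - 1;
      deme[to].push_back(deme[from][a]);
      deme[from][a] = deme[from].back(); deme[from].pop_back();
    }
  }
}

}  // namespace

// Monte-Carlo expectation of branch length classified by joint descendant
// configuration: entry [i, j] is the expected total length (in 2*N_anc
// generations) of branches subtending i pop1 tips and j pop2 tips. The
// expected unfolded joint SFS is theta/2 times this matrix.
// [[Rcpp::export]]
NumericMatrix cpp_expected_jsfs(int model, double nu1, double nu2, double Ts,
                                double Tc, double m12, double m21, int n1h,
                                int n2h, int nreps, double seed) {
  XRng rng((uint64_t)seed);
  NumericMatrix out(n1h + 1, n2h + 1);
  std::vector<double> acc((n1h + 1) * (n2h + 1), 0.0);
  for (int r = 0; r < nreps; ++r) {
    sim_genealogy(rng, model, nu1, nu2, Ts, Tc, m12, m21, n1h, n2h,
                  acc.data(), nullptr);
    if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  for (int j = 0; j <= n2h; ++j)
    for (int i = 0; i <= n1h; ++i)
      out(i, j) = acc[i + (n1h + 1) * j] / (double)nreps;
  return out;
}

// Simulate haplotypes at independently segregating loci (free recombination
// between loci, none within). theta_locus[l] = 4*N_anc*mu*L_l. Returns one
// 0/1 integer matrix (segregating sites x chromosomes) per locus; pop-1
// chromosomes first.
// [[Rcpp::export]]
List cpp_sim_haplotypes(int model, double nu1, double nu2, double Ts,
                        double Tc, double m12, double m21, int n1h, int n2h,
                        NumericVector theta_locus, double seed) {
  XRng rng((uint64_t)seed);
  const int ntips = n1h + n2h;
  const int n_loci = theta_locus.size();
  List out(n_loci);
  std::vector<int> children_head, children_next;  // intrusive child lists
  for (int l = 0; l < n_loci; ++l) {
    Tree tree;
    sim_genealogy(rng, model, nu1, nu2, Ts, Tc, m12, m21, n1h, n2h, nullptr,
                  &tree);
    const int nnode = 2 * ntips - 1;
    std::vector<double> blen(nnode, 0.0);
    double total = 0.0;
    for (int v = 0; v < nnode; ++v) {
      if (tree.parent[v] >= 0) {
        blen[v] = tree.time[tree.parent[v]] - tree.time[v];
        total += blen[v];
      }
    }
    int nmut = rng.poisson(0.5 * theta_locus[l] * total);
    IntegerMatrix haps(nmut, ntips);
    if (nmut > 0) {
      children_head.assign(nnode, -1);
      children_next.assign(nnode, -1);
      for (int v = 0; v < nnode; ++v) {
        int p = tree.parent[v];
        if (p >= 0) { children_next[v] = children_head[p]; children_head[p] = v; }
      }
      for (int m = 0; m < nmut; ++m) {
        double u = rng.unif() * total;
        int br = 0;
        for (int v = 0; v < nnode; ++v) {
          if (tree.parent[v] < 0) continue;
          if (u < blen[v]) { br = v; break; }
          u -= blen[v];
          br = v;
        }
        // mark descendant tips of br
        std::vector<int> stack;
        stack.push_back(br);
        while (!stack.empty()) {
          int v = stack.back();
          stack.pop_back();
          if (v < ntips) {
            haps(m, v) = 1;
          } else {
            for (int c = children_head[v]; c >= 0; c = children_next[c])
              stack.push_back(c);
          }
        }
      }
    }
    out[l] = haps;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
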