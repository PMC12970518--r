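// Compiled cores for covering-design construction.
//
// A design is a family of blocks (subsets of {0..n-1}, size <= k) such that
// every t-subset of the library occurs in at least `lam` distinct blocks.
// Construction is combinatorial search, so the inner loops live here; all
// validation and object assembly stays on the R side.  Indices are 0-based
// in this file and shifted by the R wrappers.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <random>
#include <set>
#include <vector>

using namespace Rcpp;

// rank of pair {i<j} within the C(n,2) pairs, row-major by smaller element
static inline long pair_rank(int i, int j, int n) {
  return (long)i * (2L * n - i - 1) / 2 + (j - i - 1);
}

// rank of triple {i<j<l}; offset of leading element i is
// C(n,3) - C(n-i,3), then pair_rank of (j,l) within the remaining n-i-1
static inline long triple_rank(int i, int j, int l, int n) {
  long c3n = (long)n * (n - 1) * (n - 2) / 6;
  long rem = (long)(n - i) * (n - i - 1) * (n - i - 2) / 6;
  return (c3n - rem) + pair_rank(j - i - 1, l - i - 1, n - i - 1);
}

static inline void sort3(int &a, int &b, int &c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
}

// ----------------------------------------------------------------- coverage
// Running state of an under-construction design: remaining multiplicity per
// t-subset, per-candidate count of uncovered subsets, total uncovered.
struct CoverState {
  int n, t, lam;
  std::vector<int> rem;        // remaining coverages needed per t-subset
  std::vector<long> incidence; // # uncovered t-subsets containing candidate
  long n_unc;
  long hits = 0; // total useful coverage decrements (progress measure)

  CoverState(int n_, int t_, int lam_) : n(n_), t(t_), lam(lam_) {
    long ns = (t == 2) ? (long)n * (n - 1) / 2
                       : (long)n * (n - 1) * (n - 2) / 6;
    rem.assign(ns, lam);
    long inc0 = (t == 2) ? (n - 1) : (long)(n - 1) * (n - 2) / 2;
    incidence.assign(n, inc0);
    n_unc = ns;
  }

  bool unc_pair(int a, int b) const {
    if (a > b) std::swap(a, b);
    return rem[pair_rank(a, b, n)] > 0;
  }
  bool unc_triple(int a, int b, int c) const {
    sort3(a, b, c);
    return rem[triple_rank(a, b, c, n)] > 0;
  }

  void hit(long idx, int a, int b) {
    if (rem[idx] > 0) {
      hits++;
      if (--rem[idx] == 0) { incidence[a]--; incidence[b]--; n_unc--; }
    }
  }
  void hit(long idx, int a, int b, int c) {
    if (rem[idx] > 0) {
      hits++;
      if (--rem[idx] == 0) {
        incidence[a]--; incidence[b]--; incidence[c]--; n_unc--;
      }
    }
  }

  // register new member x of a block with existing members `blk`
  void add(int x, const std::vector<int> &blk) {
    if (t == 2) {
      for (int m : blk) {
        int a = std::min(x, m), b = std::max(x, m);
        hit(pair_rank(a, b, n), a, b);
      }
    } else {
      for (size_t i = 0; i < blk.size(); ++i)
        for (size_t j = i + 1; j < blk.size(); ++j) {
          int a = x, b = blk[i], c = blk[j];
          sort3(a, b, c);
          hit(triple_rank(a, b, c, n), a, b, c);
        }
    }
  }

  // # uncovered t-subsets a candidate would newly touch given block `blk`
  long gain(int x, const std::vector<int> &blk) const {
    long g = 0;
    if (t == 2) {
      for (int m : blk) g += unc_pair(x, m);
    } else {
      for (size_t i = 0; i < blk.size(); ++i)
        for (size_t j = i + 1; j < blk.size(); ++j)
          g += unc_triple(x, blk[i], blk[j]);
    }
    return g;
  }

  // members of the first still-uncovered t-subset (stall guard, t = 3 only)
  std::vector<int> first_uncovered() const {
    if (t == 2) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (rem[pair_rank(i, j, n)] > 0) return {i, j};
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          for (int l = j + 1; l < n; ++l)
            if (rem[triple_rank(i, j, l, n)] > 0) return {i, j, l};
    }
    return {};
  }
};

static int pick_uniform(const std::vector<int> &v, std::mt19937 &rng) {
  std::uniform_int_distribution<size_t> d(0, v.size() - 1);
  return v[d(rng)];
}

// ------------------------------------------------------------------- greedy
// One greedy construction.  Each block position is filled by the 3-stage
// rule: (1) maximize newly covered uncovered t-subsets, (2) among ties,
// maximize membership in uncovered t-subsets, (3) uniform random tie-break.
// Every block is filled to k members even when a position covers nothing new
// (high-incidence fillers enable pairs at later positions of the same
// block, which measurably shrinks the design); only the final block may stay
// partial, when coverage completes mid-block.
static std::vector<std::vector<int>> greedy_once(int n, int k, int t, int lam,
                                                 std::mt19937 &rng) {
  CoverState st(n, t, lam);
  std::vector<std::vector<int>> blocks;

  // With lam == 1 a duplicate block would cover nothing new and is discarded
  // by the progress guard; with lam > 1 rebuilding an existing block is
  // locally optimal but designs must consist of distinct blocks, so retry
  // from a state snapshot with fresh tie-breaks.
  std::set<std::vector<int>> seen;
  int dup_retries = 0;

  bool force_seed = false; // t = 3 stall guard
  while (st.n_unc > 0) {
    CoverState snapshot = (lam > 1) ? st : CoverState(2, 2, 1);
    std::vector<int> blk;
    std::vector<char> inblk(n, 0);
    std::vector<long> gain(n, 0); // maintained incrementally for t = 2
    long hits_at_start = st.hits;

    if (force_seed) {
      for (int m : st.first_uncovered()) {
        st.add(m, blk);
        blk.push_back(m);
        inblk[m] = 1;
        if (t == 2)
          for (int c = 0; c < n; ++c)
            if (!inblk[c]) gain[c] += st.unc_pair(c, m);
      }
      force_seed = false;
    }

    while ((int)blk.size() < k && st.n_unc > 0) {
      long best = -1;
      if (t == 2) {
        for (int c = 0; c < n; ++c)
          if (!inblk[c] && gain[c] > best) best = gain[c];
      } else {
        for (int c = 0; c < n; ++c) {
          if (inblk[c]) continue;
          gain[c] = st.gain(c, blk);
          if (gain[c] > best) best = gain[c];
        }
      }
      long best_inc = -1;
      for (int c = 0; c < n; ++c)
        if (!inblk[c] && gain[c] == best && st.incidence[c] > best_inc)
          best_inc = st.incidence[c];
      std::vector<int> finalists;
      for (int c = 0; c < n; ++c)
        if (!inblk[c] && gain[c] == best && st.incidence[c] == best_inc)
          finalists.push_back(c);

      int chosen = pick_uniform(finalists, rng);
      st.add(chosen, blk);
      blk.push_back(chosen);
      inblk[chosen] = 1;
      if (t == 2)
        for (int c = 0; c < n; ++c)
          if (!inblk[c]) gain[c] += st.unc_pair(c, chosen);
    }

    if (st.hits == hits_at_start) {
      // block contributed no coverage at all (possible for t = 3 when the
      // chosen opening members share no uncovered triple): discard it and
      // seed the next block directly from an uncovered subset
      force_seed = true;
      continue;
    }
    std::sort(blk.begin(), blk.end());
    if (lam > 1) {
      if (seen.count(blk)) {
        st = snapshot; // undo this block's coverage and retry
        if (++dup_retries > 50) {
          // random completion of an uncovered subset, rejected against seen
          std::vector<int> pool(n);
          for (int i = 0; i < n; ++i) pool[i] = i;
          std::vector<int> base = st.first_uncovered();
          for (int tries = 0; tries < 500; ++tries) {
            std::shuffle(pool.begin(), pool.end(), rng);
            std::vector<int> cand(base);
            for (int c : pool) {
              if ((int)cand.size() >= k) break;
              if (std::find(cand.begin(), cand.end(), c) == cand.end())
                cand.push_back(c);
            }
            std::sort(cand.begin(), cand.end());
            if (!seen.count(cand)) {
              std::vector<int> cur;
              for (int m : cand) { st.add(m, cur); cur.push_back(m); }
              seen.insert(cand);
              blocks.push_back(cand);
              break;
            }
          }
          dup_retries = 0;
        }
        continue;
      }
      seen.insert(blk);
    }
    blocks.push_back(blk);
  }
  return blocks;
}

// [[Rcpp::export]]
List greedy_design_cpp(int n, int k, int t, int lam, int restarts, int seed) {
  std::mt19937 rng((uint32_t)seed);
  std::vector<std::vector<int>> best;
  bool have = false;
  for (int r = 0; r < restarts; ++r) {
    if (r % 16 == 0) Rcpp::checkUserInterrupt();
    std::vector<std::vector<int>> cand = greedy_once(n, k, t, lam, rng);
    if (!have || cand.size() < best.size()) {
      best = cand;
      have = true;
    }
  }
  List out(best.size());
  for (size_t i = 0; i < best.size(); ++i)
    out[i] = IntegerVector(best[i].begin(), best[i].end());
  return out;
}

// --------------------------------------------------------------------- swap
// Hill climbing over families of exactly n_blocks blocks of size k: swap one
// block member for a non-member whenever that strictly increases total
// coverage sum(min(count, lam)); best improving swap, random tie-break;
// restart from a fresh random family when stalled, within a global budget
// of max_iters applied moves.

struct SwapState {
  int n, k, t, lam, n_blocks;
  std::vector<std::vector<int>> blocks;
  std::vector<int> cnt;  // blocks covering each t-subset
  long deficient;        // # t-subsets with cnt < lam

  SwapState(int n_, int k_, int t_, int lam_, int nb)
      : n(n_), k(k_), t(t_), lam(lam_), n_blocks(nb) {}

  long nsub() const {
    return (t == 2) ? (long)n * (n - 1) / 2 : (long)n * (n - 1) * (n - 2) / 6;
  }

  void randomize(std::mt19937 &rng) {
    blocks.assign(n_blocks, {});
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int b = 0; b < n_blocks; ++b) {
      std::shuffle(perm.begin(), perm.end(), rng);
      blocks[b].assign(perm.begin(), perm.begin() + k);
      std::sort(blocks[b].begin(), blocks[b].end());
    }
    recount();
  }

  void recount() {
    cnt.assign(nsub(), 0);
    for (auto &blk : blocks) bump(blk, +1);
    deficient = 0;
    for (long i = 0; i < (long)cnt.size(); ++i)
      if (cnt[i] < lam) deficient++;
  }

  void bump(const std::vector<int> &blk, int d) {
    int m = blk.size();
    if (t == 2) {
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          cnt[pair_rank(blk[i], blk[j], n)] += d;
    } else {
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          for (int l = j + 1; l < m; ++l)
            cnt[triple_rank(blk[i], blk[j], blk[l], n)] += d;
    }
  }

  // coverage change if member x of block b is replaced by outsider y;
  // fills rm/ad with the t-subset ranks that lose/gain a covering block
  long eval(int b, int x, int y, std::vector<long> &rm, std::vector<long> &ad) const {
    rm.clear(); ad.clear();
    const std::vector<int> &blk = blocks[b];
    long d = 0;
    if (t == 2) {
      for (int m : blk) {
        if (m == x) continue;
        long ir = pair_rank(std::min(x, m), std::max(x, m), n);
        long ia = pair_rank(std::min(y, m), std::max(y, m), n);
        rm.push_back(ir); ad.push_back(ia);
        if (cnt[ir] <= lam) d--;
        if (cnt[ia] < lam) d++;
      }
    } else {
      for (size_t i = 0; i < blk.size(); ++i)
        for (size_t j = i + 1; j < blk.size(); ++j) {
          if (blk[i] == x || blk[j] == x) continue;
          int a1 = x, b1 = blk[i], c1 = blk[j];
          sort3(a1, b1, c1);
          int a2 = y, b2 = blk[i], c2 = blk[j];
          sort3(a2, b2, c2);
          long ir = triple_rank(a1, b1, c1, n), ia = triple_rank(a2, b2, c2, n);
          rm.push_back(ir); ad.push_back(ia);
          if (cnt[ir] <= lam) d--;
          if (cnt[ia] < lam) d++;
        }
    }
    return d;
  }

  void apply(int b, int x, int y, const std::vector<long> &rm,
             const std::vector<long> &ad) {
    for (long idx : rm) {
      cnt[idx]--;
      if (cnt[idx] == lam - 1) deficient++;
    }
    for (long idx : ad) {
      cnt[idx]++;
      if (cnt[idx] == lam) deficient--;
    }
    std::vector<int> &blk = blocks[b];
    *std::find(blk.begin(), blk.end(), x) = y;
    std::sort(blk.begin(), blk.end());
  }
};

// [[Rcpp::export]]
List swap_design_cpp(int n, int k, int t, int lam, int n_blocks,
                     int max_iters, int seed) {
  std::mt19937 rng((uint32_t)seed);
  SwapState st(n, k, t, lam, n_blocks);
  st.randomize(rng);

  std::vector<std::vector<int>> best_blocks = st.blocks;
  long best_def = st.deficient;

  std::vector<long> rm, ad, rm_b, ad_b;
  int iters = 0;
  while (st.deficient > 0 && iters < max_iters) {
    Rcpp::checkUserInterrupt();
    long best_d = 0;
    std::vector<std::array<int, 3>> ties;
    std::vector<char> inblk(n, 0);
    for (int b = 0; b < n_blocks; ++b) {
      std::fill(inblk.begin(), inblk.end(), 0);
      for (int m : st.blocks[b]) inblk[m] = 1;
      for (int xi = 0; xi < k; ++xi) {
        int x = st.blocks[b][xi];
        for (int y = 0; y < n; ++y) {
          if (inblk[y]) continue;
          long d = st.eval(b, x, y, rm, ad);
          if (d > best_d) {
            best_d = d;
            ties.clear();
            ties.push_back({b, x, y});
          } else if (d == best_d && d > 0) {
            ties.push_back({b, x, y});
          }
        }
      }
    }
    if (best_d > 0) {
      std::uniform_int_distribution<size_t> u(0, ties.size() - 1);
      auto mv = ties[u(rng)];
      st.eval(mv[0], mv[1], mv[2], rm_b, ad_b);
      st.apply(mv[0], mv[1], mv[2], rm_b, ad_b);
      iters++;
      if (st.deficient < best_def) {
        best_def = st.deficient;
        best_blocks = st.blocks;
      }
    } else {
      // local optimum short of full coverage: fresh random restart
      st.randomize(rng);
      iters++;
      if (st.deficient < best_def) {
        best_def = st.deficient;
        best_blocks = st.blocks;
      }
    }
  }
  if (st.deficient < best_def) {
    best_def = st.deficient;
    best_blocks = st.blocks;
  }

  List blks(best_blocks.size());
  for (size_t i = 0; i < best_blocks.size(); ++i)
    blks[i] = IntegerVector(best_blocks[i].begin(), best_blocks[i].end());
  return List::create(_["blocks"] = blks,
                      _["complete"] = (best_def == 0),
                      _["uncovered"] = (double)best_def,
                      _["iters"] = iters);
}
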