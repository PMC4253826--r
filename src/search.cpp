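#include "kidx.h"

#include <algorithm>
#include <cmath>
#include <climits>
#include <vector>

using namespace Rcpp;

// Depth-first path search in the de Bruijn graph with node-wise
// edit-distance DP rows against a read region.  Children are explored in
// appended-base order A<C<G<T; the branching counter increments each time
// a non-first existing alternative is taken, and exceeding the limit
// aborts the whole search (candidates found so far are discarded).

namespace {

struct BridgeSearcher {
  const KIdx &G;
  const std::vector<int> &reg;  // region base codes, -1 never matches
  int n, E, maxlen;
  long branching_limit;
  uint64_t tf;  // target in the read's orientation
  long branches;
  bool aborted;
  int best;
  std::string bestpath;
  std::string path;
  std::vector<std::vector<int> > rows;  // rows[i]: DP row after i path bases

  BridgeSearcher(const KIdx &g, const std::vector<int> &r, int E_, int maxlen_,
                 long blim, uint64_t tf_)
      : G(g),
        reg(r),
        n((int)r.size()),
        E(E_),
        maxlen(maxlen_),
        branching_limit(blim),
        tf(tf_),
        branches(0),
        aborted(false),
        best(INT_MAX) {}

  void dfs(uint64_t fwd, uint64_t rc) {
    int m = (int)path.size();
    if (fwd == tf && m >= G.k) {
      int d = rows[(size_t)m][(size_t)n];
      if (d <= E && d < best) {
        best = d;
        bestpath = path;
      }
    }
    if (m >= maxlen) return;
    int child_idx = 0;
    for (int b = 0; b < 4; ++b) {
      uint64_t f = fwd, r = rc;
      G.step_right(f, r, b);
      if (!G.count_ok(f, r)) continue;
      if (child_idx > 0 && ++branches > branching_limit) {
        aborted = true;
        return;
      }
      ++child_idx;
      if ((int)rows.size() <= m + 1)
        rows.push_back(std::vector<int>((size_t)n + 1));
      std::vector<int> &nr = rows[(size_t)m + 1];
      const std::vector<int> &pr = rows[(size_t)m];
      nr[0] = m + 1;
      int mn = nr[0];
      for (int j = 1; j <= n; ++j) {
        int v = pr[(size_t)j - 1] + (reg[(size_t)j - 1] == b ? 0 : 1);
        int d2 = nr[(size_t)j - 1] + 1;
        if (d2 < v) v = d2;
        int e2 = pr[(size_t)j] + 1;
        if (e2 < v) v = e2;
        nr[(size_t)j] = v;
        if (v < mn) mn = v;
      }
      if (mn > E) continue;  // no extension of this path can fit the budget
      path.push_back(int2base(b));
      dfs(f, r);
      path.pop_back();
      if (aborted) return;
    }
  }
};

void seed_rows(std::vector<std::vector<int> > &rows, const std::string &seedseq,
               const std::vector<int> &reg) {
  int n = (int)reg.size();
  rows.clear();
  rows.push_back(std::vector<int>((size_t)n + 1));
  for (int j = 0; j <= n; ++j) rows[0][(size_t)j] = j;
  for (size_t i = 0; i < seedseq.size(); ++i) {
    int b = base2int(seedseq[i]);
    rows.push_back(std::vector<int>((size_t)n + 1));
    std::vector<int> &nr = rows[i + 1];
    const std::vector<int> &pr = rows[i];
    nr[0] = (int)i + 1;
    for (int j = 1; j <= n; ++j) {
      int v = pr[(size_t)j - 1] + (reg[(size_t)j - 1] == b ? 0 : 1);
      int d2 = nr[(size_t)j - 1] + 1;
      if (d2 < v) v = d2;
      int e2 = pr[(size_t)j] + 1;
      if (e2 < v) v = e2;
      nr[(size_t)j] = v;
    }
  }
}

std::vector<int> encode_region(const std::string &s) {
  std::vector<int> reg(s.size());
  for (size_t i = 0; i < s.size(); ++i) reg[i] = base2int(s[i]);
  return reg;
}

}  // namespace

// [[Rcpp::export]]
List cx_bridge_search(SEXP xp_, std::string source, std::string target,
                      std::string region, double max_error_rate,
                      int branching_limit) {
  XPtr<KIdx> xp(xp_);
  const KIdx &G = *xp;
  int k = G.k;
  int n = (int)region.size();
  uint64_t sf, sr, tf, tr;
  if (!encode_kmer(source, k, sf, sr)) stop("invalid source k-mer");
  if (!encode_kmer(target, k, tf, tr)) stop("invalid target k-mer");
  if (n < 2 * k) stop("region shorter than 2k: anchors must not overlap");
  std::vector<int> reg = encode_region(region);
  int E = (int)std::ceil(max_error_rate * n);
  BridgeSearcher S(G, reg, E, n + E, branching_limit, tf);
  seed_rows(S.rows, source, reg);
  S.path = source;
  // the seed itself may already blow the budget
  int mn = INT_MAX;
  for (int j = 0; j <= n; ++j) mn = std::min(mn, S.rows[(size_t)k][(size_t)j]);
  if (mn <= E) S.dfs(sf, sr);
  std::string status = S.aborted
                           ? "ABORTED"
                           : (S.best < INT_MAX ? "FOUND" : "NO_PATH");
  List out = List::create(
      _["status"] = status,
      _["path_seq"] = (status == "FOUND") ? wrap(S.bestpath) : R_NilValue,
      _["edit_dist"] = (status == "FOUND") ? wrap(S.best) : R_NilValue,
      _["branches"] = (double)S.branches, _["error_budget"] = E);
  return out;
}

namespace {

// Extension search (tail direction): grow paths from the anchor, keep the
// admissible path maximising (length, then row-minimum edit distance).
struct ExtSearcher {
  const KIdx &G;
  const std::vector<int> &reg;
  int n, maxlen;
  double rate;
  long branching_limit;
  long branches;
  bool aborted;
  int best_m;
  int best_d;
  std::string bestpath;
  std::string path;
  std::vector<std::vector<int> > rows;

  ExtSearcher(const KIdx &g, const std::vector<int> &r, int maxlen_,
              double rate_, long blim)
      : G(g),
        reg(r),
        n((int)r.size()),
        maxlen(maxlen_),
        rate(rate_),
        branching_limit(blim),
        branches(0),
        aborted(false),
        best_m(-1),
        best_d(INT_MAX) {}

  void dfs(uint64_t fwd, uint64_t rc) {
    int m = (int)path.size();
    if (m >= maxlen) return;
    int child_idx = 0;
    for (int b = 0; b < 4; ++b) {
      uint64_t f = fwd, r = rc;
      G.step_right(f, r, b);
      if (!G.count_ok(f, r)) continue;
      if (child_idx > 0 && ++branches > branching_limit) {
        aborted = true;
        return;
      }
      ++child_idx;
      if ((int)rows.size() <= m + 1)
        rows.push_back(std::vector<int>((size_t)n + 1));
      std::vector<int> &nr = rows[(size_t)m + 1];
      const std::vector<int> &pr = rows[(size_t)m];
      nr[0] = m + 1;
      int mn = nr[0];
      for (int j = 1; j <= n; ++j) {
        int v = pr[(size_t)j - 1] + (reg[(size_t)j - 1] == b ? 0 : 1);
        int d2 = nr[(size_t)j - 1] + 1;
        if (d2 < v) v = d2;
        int e2 = pr[(size_t)j] + 1;
        if (e2 < v) v = e2;
        nr[(size_t)j] = v;
        if (v < mn) mn = v;
      }
      // linear drop-off: abandon once errors outgrow the admissible rate
      if ((double)mn > rate * (m + 1)) continue;
      path.push_back(int2base(b));
      if (m + 1 > best_m || (m + 1 == best_m && mn < best_d)) {
        best_m = m + 1;
        best_d = mn;
        bestpath = path;
      }
      dfs(f, r);
      path.pop_back();
      if (aborted) return;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cx_extension_search(SEXP xp_, std::string anchor, std::string segment,
                         double max_error_rate, int branching_limit) {
  XPtr<KIdx> xp(xp_);
  const KIdx &G = *xp;
  int k = G.k;
  int n = (int)segment.size();
  uint64_t af, ar;
  if (!encode_kmer(anchor, k, af, ar)) stop("invalid anchor k-mer");
  if (n < k) stop("segment shorter than the anchor k-mer");
  std::vector<int> reg = encode_region(segment);
  int E = (int)std::ceil(max_error_rate * n);
  ExtSearcher S(G, reg, n + E, max_error_rate, branching_limit);
  seed_rows(S.rows, anchor, reg);
  S.path = anchor;
  S.best_m = -1;
  S.dfs(af, ar);
  std::string status;
  if (S.aborted)
    status = "ABORTED";
  else if (S.best_m <= k)
    status = "NO_PATH";  // never extended past the anchor
  else
    status = "FOUND";
  return List::create(
      _["status"] = status,
      _["path_seq"] = (status == "FOUND") ? wrap(S.bestpath) : R_NilValue,
      _["branches"] = (double)S.branches);
}

// Best prefix of `path` under global alignment against any prefix of
// `segment`; match +1, mismatch -1, gap -1.  Ties prefer the longer path
// prefix, then the longer segment prefix.  Prefixes shorter than min_len
// (the anchor) are not considered.
// [[Rcpp::export]]
List cx_best_prefix_alignment(std::string path, std::string segment,
                              int min_len) {
  int P = (int)path.size(), n = (int)segment.size();
  if (min_len < 0 || min_len > P) stop("min_len out of range");
  std::vector<int> prev((size_t)n + 1), cur((size_t)n + 1);
  for (int j = 0; j <= n; ++j) prev[(size_t)j] = -j;
  int best_i = -1, best_j = -1, best_score = INT_MIN;
  if (min_len == 0) {
    best_i = 0;
    best_j = 0;
    best_score = 0;
  }
  for (int i = 1; i <= P; ++i) {
    cur[0] = -i;
    int row_best = cur[0], row_j = 0;
    for (int j = 1; j <= n; ++j) {
      int v = prev[(size_t)j - 1] +
              (path[(size_t)i - 1] == segment[(size_t)j - 1] ? 1 : -1);
      int d2 = prev[(size_t)j] - 1;
      if (d2 > v) v = d2;
      int e2 = cur[(size_t)j - 1] - 1;
      if (e2 > v) v = e2;
      cur[(size_t)j] = v;
      if (v >= row_best) {  // >= : tie toward longer segment prefix
        row_best = v;
        row_j = j;
      }
    }
    if (i >= min_len && row_best >= best_score) {  // >= : tie toward longer
      best_score = row_best;
      best_i = i;
      best_j = row_j;
    }
    std::swap(prev, cur);
  }
  return List::create(_["length"] = best_i, _["seg_length"] = best_j,
                      _["score"] = best_score);
}
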