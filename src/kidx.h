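#ifndef LREC_KIDX_H
#define LREC_KIDX_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>

// 2-bit base codes; order A<C<G<T matches lexicographic order, so the
// numeric minimum of (fwd, revcomp) encodings is the canonical k-mer.
inline int base2int(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char int2base(int b) { return "ACGT"[b & 3]; }

// Exact hash-based index of canonical k-mer counts (k <= 31).
struct KIdx {
  int k;
  int threshold;
  bool require_arcs;
  uint64_t mask;
  std::unordered_map<uint64_t, int> counts;

  KIdx(int k_, int thr, bool arcs)
      : k(k_), threshold(thr), require_arcs(arcs) {
    mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  }

  inline uint64_t canon(uint64_t fwd, uint64_t rc) const {
    return fwd < rc ? fwd : rc;
  }
  inline int count_of(uint64_t fwd, uint64_t rc) const {
    std::unordered_map<uint64_t, int>::const_iterator it =
        counts.find(canon(fwd, rc));
    return it == counts.end() ? 0 : it->second;
  }
  inline bool count_ok(uint64_t fwd, uint64_t rc) const {
    return count_of(fwd, rc) >= threshold;
  }
  // append base b on the right: k-mer[1:] + b
  inline void step_right(uint64_t &fwd, uint64_t &rc, int b) const {
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
  }
  // prepend base b on the left: b + k-mer[:-1]
  inline void step_left(uint64_t &fwd, uint64_t &rc, int b) const {
    fwd = (fwd >> 2) | ((uint64_t)b << (2 * (k - 1)));
    rc = ((rc << 2) | (uint64_t)(3 - b)) & mask;
  }
  inline bool has_right(uint64_t fwd, uint64_t rc) const {
    for (int b = 0; b < 4; ++b) {
      uint64_t f = fwd, r = rc;
      step_right(f, r, b);
      if (count_ok(f, r)) return true;
    }
    return false;
  }
  inline bool has_left(uint64_t fwd, uint64_t rc) const {
    for (int b = 0; b < 4; ++b) {
      uint64_t f = fwd, r = rc;
      step_left(f, r, b);
      if (count_ok(f, r)) return true;
    }
    return false;
  }
  // full solidity: count threshold plus (optionally) >=1 in and out arc
  inline bool solid(uint64_t fwd, uint64_t rc) const {
    if (!count_ok(fwd, rc)) return false;
    if (!require_arcs) return true;
    return has_right(fwd, rc) && has_left(fwd, rc);
  }
};

// Encode a k-length ACGT string; false if wrong length or non-ACGT.
inline bool encode_kmer(const std::string &s, int k, uint64_t &fwd,
                        uint64_t &rc) {
  if ((int)s.size() != k) return false;
  fwd = 0;
  rc = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2int(s[i]);
    if (b < 0) return false;
    fwd = (fwd << 2) | (uint64_t)b;
    rc |= ((uint64_t)(3 - b)) << (2 * i);
  }
  return true;
}

inline std::string decode_kmer(uint64_t x, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = int2base((int)(x & 3));
    x >>= 2;
  }
  return s;
}

#endif
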