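#include "kidx.h"

#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
SEXP cx_build_index(CharacterVector reads, int k, int threshold,
                    bool require_arcs) {
  XPtr<KIdx> xp(new KIdx(k, threshold, require_arcs), true);
  KIdx &G = *xp;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    uint64_t fwd = 0, rc = 0;
    int run = 0;  // contiguous valid bases ending here; windows with N skipped
    for (const char *p = s; *p; ++p) {
      int b = base2int(*p);
      if (b < 0) {
        run = 0;
        fwd = rc = 0;
        continue;
      }
      fwd = ((fwd << 2) | (uint64_t)b) & G.mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) G.counts[G.canon(fwd, rc)] += 1;
    }
  }
  return xp;
}

// [[Rcpp::export]]
SEXP cx_index_from_counts(CharacterVector kmers, IntegerVector counts, int k,
                          int threshold, bool require_arcs) {
  if (kmers.size() != counts.size()) stop("kmers and counts lengths differ");
  XPtr<KIdx> xp(new KIdx(k, threshold, require_arcs), true);
  KIdx &G = *xp;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t fwd, rc;
    if (!encode_kmer(s, k, fwd, rc)) stop("invalid k-mer: %s", s.c_str());
    if (counts[i] < 1) stop("counts must be positive");
    G.counts[G.canon(fwd, rc)] += counts[i];
  }
  return xp;
}

// [[Rcpp::export]]
List cx_index_info(SEXP xp_) {
  XPtr<KIdx> xp(xp_);
  double total = 0;
  for (std::unordered_map<uint64_t, int>::const_iterator it =
           xp->counts.begin();
       it != xp->counts.end(); ++it)
    total += it->second;
  return List::create(_["k"] = xp->k, _["solid_threshold"] = xp->threshold,
                      _["require_arcs"] = xp->require_arcs,
                      _["n_kmers"] = (double)xp->counts.size(),
                      _["total_count"] = total);
}

// [[Rcpp::export]]
DataFrame cx_index_dump(SEXP xp_) {
  XPtr<KIdx> xp(xp_);
  std::vector<uint64_t> keys;
  keys.reserve(xp->counts.size());
  for (std::unordered_map<uint64_t, int>::const_iterator it =
           xp->counts.begin();
       it != xp->counts.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());  // numeric order == lexicographic
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], xp->k);
    ct[i] = xp->counts.find(keys[i])->second;
  }
  return DataFrame::create(_["kmer"] = km, _["count"] = ct,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cx_canonical(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    int k = (int)s.size();
    if (k < 1 || k > 31 || k % 2 == 0)
      stop("k-mer length must be odd and at most 31, got %d", k);
    uint64_t fwd, rc;
    if (!encode_kmer(s, k, fwd, rc))
      stop("k-mer contains a non-ACGT character: %s", s.c_str());
    out[i] = decode_kmer(fwd < rc ? fwd : rc, k);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cx_kmer_count(SEXP xp_, CharacterVector kmers) {
  XPtr<KIdx> xp(xp_);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t fwd, rc;
    if (!encode_kmer(s, xp->k, fwd, rc))
      stop("invalid k-mer (length %d expected, ACGT only): %s", xp->k,
           s.c_str());
    out[i] = xp->count_of(fwd, rc);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cx_is_solid(SEXP xp_, CharacterVector kmers) {
  XPtr<KIdx> xp(xp_);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t fwd, rc;
    if (!encode_kmer(s, xp->k, fwd, rc))
      stop("invalid k-mer (length %d expected, ACGT only): %s", xp->k,
           s.c_str());
    out[i] = xp->solid(fwd, rc);
  }
  return out;
}

// Neighbours in the query's own orientation, appended/prepended base in
// A<C<G<T order; membership is by count threshold (canonical lookup).
// [[Rcpp::export]]
CharacterVector cx_neighbors(SEXP xp_, std::string kmer, bool forward) {
  XPtr<KIdx> xp(xp_);
  uint64_t fwd, rc;
  if (!encode_kmer(kmer, xp->k, fwd, rc))
    stop("invalid k-mer (length %d expected, ACGT only): %s", xp->k,
         kmer.c_str());
  std::vector<std::string> hits;
  for (int b = 0; b < 4; ++b) {
    uint64_t f = fwd, r = rc;
    if (forward)
      xp->step_right(f, r, b);
    else
      xp->step_left(f, r, b);
    if (xp->count_ok(f, r)) hits.push_back(decode_kmer(f, xp->k));
  }
  return wrap(hits);
}

// Solidity flag for every k-mer start position of a read (length n-k+1);
// windows containing non-ACGT characters are weak.
// [[Rcpp::export]]
LogicalVector cx_classify_read(SEXP xp_, std::string read) {
  XPtr<KIdx> xp(xp_);
  const KIdx &G = *xp;
  int k = G.k;
  int n = (int)read.size();
  if (n < k) return LogicalVector(0);
  LogicalVector out(n - k + 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2int(read[(size_t)i]);
    if (b < 0) {
      run = 0;
      fwd = rc = 0;
      if (i >= k - 1) out[i - k + 1] = false;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & G.mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    ++run;
    if (i >= k - 1) out[i - k + 1] = (run >= k) && G.solid(fwd, rc);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cx_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      char o;
      switch (c) {
        case 'A': o = 'T'; break;
        case 'C': o = 'G'; break;
        case 'G': o = 'C'; break;
        case 'T': o = 'A'; break;
        case 'a': o = 't'; break;
        case 'c': o = 'g'; break;
        case 'g': o = 'c'; break;
        case 't': o = 'a'; break;
        case 'N': o = 'N'; break;
        case 'n': o = 'n'; break;
        default:
          stop("cannot reverse-complement character '%c'", c);
      }
      r[j] = o;
    }
    out[i] = r;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
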