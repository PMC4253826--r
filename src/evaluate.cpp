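#include <Rcpp.h>

#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Global unit-cost edit alignment of `read` against `truth` with a
// deterministic traceback: prefer match/mismatch, then deletion (truth base
// absent from the read), then insertion (extra read base).  Returns one op
// per alignment column: M match, X mismatch, D deletion, I insertion.
// [[Rcpp::export]]
std::string cx_align_ops(std::string read, std::string truth) {
  int n = (int)read.size(), L = (int)truth.size();
  if ((double)(n + 1) * (double)(L + 1) > 6.5e8)
    stop("sequences too long for full edit alignment");
  if (n + L >= 65000) stop("combined sequence length exceeds 65000");
  std::vector<uint16_t> D((size_t)(n + 1) * (size_t)(L + 1));
  size_t W = (size_t)L + 1;
  for (int j = 0; j <= L; ++j) D[(size_t)j] = (uint16_t)j;
  for (int i = 1; i <= n; ++i) {
    D[(size_t)i * W] = (uint16_t)i;
    const char ci = read[(size_t)i - 1];
    for (int j = 1; j <= L; ++j) {
      uint16_t v = (uint16_t)(D[(size_t)(i - 1) * W + (size_t)(j - 1)] +
                              (ci == truth[(size_t)j - 1] ? 0 : 1));
      uint16_t d2 = (uint16_t)(D[(size_t)i * W + (size_t)(j - 1)] + 1);
      if (d2 < v) v = d2;
      uint16_t e2 = (uint16_t)(D[(size_t)(i - 1) * W + (size_t)j] + 1);
      if (e2 < v) v = e2;
      D[(size_t)i * W + (size_t)j] = v;
    }
  }
  std::string ops;
  ops.reserve((size_t)(n + L));
  int i = n, j = L;
  while (i > 0 || j > 0) {
    uint16_t here = D[(size_t)i * W + (size_t)j];
    if (i > 0 && j > 0) {
      bool m = (read[(size_t)i - 1] == truth[(size_t)j - 1]);
      if (D[(size_t)(i - 1) * W + (size_t)(j - 1)] + (m ? 0 : 1) == here) {
        ops.push_back(m ? 'M' : 'X');
        --i;
        --j;
        continue;
      }
    }
    if (j > 0 && D[(size_t)i * W + (size_t)(j - 1)] + 1 == here) {
      ops.push_back('D');
      --j;
      continue;
    }
    ops.push_back('I');
    --i;
  }
  std::reverse(ops.begin(), ops.end());
  return ops;
}
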