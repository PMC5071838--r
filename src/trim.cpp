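// 3' adapter search: leftmost start where a prefix of the adapter matches
// the read with a bounded number of substitutions over at least
// min_overlap bases (the adapter may run off the read's 3' end).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".adapter_cut_cpp")]]
IntegerVector adapter_cut_cpp(CharacterVector reads, std::string adapter,
                              int min_overlap, int max_mm) {
  const int alen = (int) adapter.size();
  IntegerVector cut(reads.size(), NA_INTEGER);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    if (reads[i] == NA_STRING) continue;
    std::string r = as<std::string>(reads[i]);
    const int L = (int) r.size();
    for (int s = 0; s + min_overlap <= L; ++s) {
      const int k = std::min(alen, L - s);
      if (k < min_overlap) break;
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (r[s + j] != adapter[j] && ++mm > max_mm) { ok = false; break; }
      }
      if (ok) { cut[i] = s + 1; break; }   // 1-based adapter start
    }
  }
  return cut;
}
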