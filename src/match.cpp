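// Ungapped full-length matching with a bounded Hamming distance --
// the <=1-mismatch mapping primitive (Bowtie-style -v 1 semantics,
// substitutions only). Characters compare literally (uppercase ACGTN);
// an N spacer in a concatenated subject can never be crossed because any
// window overlapping it exceeds the mismatch budget for real tags.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".hamming_scan_cpp")]]
List hamming_scan_cpp(std::string pattern, std::string subject, int max_mm) {
  const int m = (int) pattern.size(), n = (int) subject.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if (subject[s + j] != pattern[j] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) { starts.push_back(s); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}

// [[Rcpp::export(name = ".any_hit_cpp")]]
LogicalVector any_hit_cpp(CharacterVector patterns, std::string subject,
                          int max_mm) {
  const int n = (int) subject.size();
  LogicalVector out(patterns.size());
  for (R_xlen_t i = 0; i < patterns.size(); ++i) {
    std::string p = as<std::string>(patterns[i]);
    const int m = (int) p.size();
    bool hit = false;
    for (int s = 0; s + m <= n && !hit; ++s) {
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < m; ++j) {
        if (subject[s + j] != p[j] && ++mm > max_mm) { ok = false; break; }
      }
      hit = ok;
    }
    out[i] = hit;
  }
  return out;
}
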