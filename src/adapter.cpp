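#include <Rcpp.h>
using namespace Rcpp;

// Leftmost 1-based position in each read from which the read suffix matches
// a prefix of the adapter with at most max_mismatch mismatches and an
// overlap of at least min_overlap bases.  NA when no such position exists.
// [[Rcpp::export]]
IntegerVector adapter_pos_cpp(CharacterVector reads, std::string adapter,
                              int min_overlap, int max_mismatch) {
  int n = reads.size(), alen = adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int rlen = r.size();
    int hit = NA_INTEGER;
    for (int j = 0; j + min_overlap <= rlen; ++j) {
      int overlap = std::min(rlen - j, alen);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < overlap; ++k) {
        if (r[j + k] != adapter[k] && ++mm > max_mismatch) { ok = false; break; }
      }
      if (ok) { hit = j + 1; break; }
    }
    out[i] = hit;
  }
  return out;
}
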