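#include <Rcpp.h>
using namespace Rcpp;

// Candidate enumeration for one read against every mature entry.
//
// Alignment model: the read 5' end is placed at hairpin position
// p = start - shift5 (0-based).  For a tail length t the templated span is
// the read minus its last t bases, aligned base-by-base against the hairpin
// from p.  shift3 = (p + span) - end.  A candidate is valid when
//   * the templated span lies within the hairpin,
//   * |shift5| <= max5, |shift3| <= max3, t <= maxtail,
//   * mismatches within the span <= maxmm, and a mismatch forces
//     shift5 == shift3 == 0, t == 0 and an internal position
//     (not the first or last base of the read),
//   * the tail is maximal: its first base does not match the hairpin at its
//     own position (templated explanations take precedence over tails).
//
// Returns one row per (entry, shift5, t) candidate with its edit total
// (mismatches + |shift5| + |shift3| + t).  Class assignment and tie
// resolution are done in R.
// [[Rcpp::export]]
DataFrame classify_candidates_cpp(std::string read,
                                  CharacterVector hairpin_seq,
                                  IntegerVector start,
                                  IntegerVector end,
                                  int max5, int max3, int maxtail, int maxmm) {
  int n = read.size();
  std::vector<int> c_entry, c_shift5, c_shift3, c_tail, c_mm, c_mpos, c_edits;
  std::vector<std::string> c_tailseq, c_from, c_to;

  for (int e = 0; e < hairpin_seq.size(); ++e) {
    std::string H = as<std::string>(hairpin_seq[e]);
    int lenH = H.size();
    int st = start[e], en = end[e];
    for (int shift5 = -max5; shift5 <= max5; ++shift5) {
      int p = st - shift5;
      if (p < 0 || p >= lenH) continue;
      for (int t = 0; t <= maxtail && t < n; ++t) {
        int span = n - t;
        if (p + span > lenH) continue;  // captured at larger t (flush) if any
        // maximality of the tail
        if (t > 0 && p + span < lenH && read[span] == H[p + span]) continue;
        int shift3 = (p + span) - en;
        if (shift3 < -max3 || shift3 > max3) continue;
        int mm = 0, mpos = -1;
        for (int k = 0; k < span; ++k) {
          if (read[k] != H[p + k]) {
            ++mm;
            mpos = k;
            if (mm > maxmm) break;
          }
        }
        if (mm > maxmm) continue;
        if (mm > 0) {
          if (shift5 != 0 || shift3 != 0 || t != 0) continue;
          if (mpos == 0 || mpos == n - 1) continue;  // terminal: not NucVar
        }
        c_entry.push_back(e + 1);
        c_shift5.push_back(shift5);
        c_shift3.push_back(shift3);
        c_tail.push_back(t);
        c_tailseq.push_back(read.substr(span, t));
        c_mm.push_back(mm);
        c_mpos.push_back(mm > 0 ? mpos + 1 : NA_INTEGER);
        c_from.push_back(mm > 0 ? std::string(1, H[p + mpos]) : std::string(""));
        c_to.push_back(mm > 0 ? std::string(1, read[mpos]) : std::string(""));
        c_edits.push_back(mm + std::abs(shift5) + std::abs(shift3) + t);
      }
    }
  }
  return DataFrame::create(
    _["entry"] = c_entry, _["shift5"] = c_shift5, _["shift3"] = c_shift3,
    _["tail_len"] = c_tail, _["tail"] = c_tailseq, _["mm"] = c_mm,
    _["subst_pos"] = c_mpos, _["subst_from"] = c_from, _["subst_to"] = c_to,
    _["edits"] = c_edits, _["stringsAsFactors"] = false);
}
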