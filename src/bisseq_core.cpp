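#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exhaustive overlap scan for merging a read pair. Mate 2 arrives already
// reverse-complemented (quality reversed). For every overlap length
// o >= min_overlap the score is the number of matched bases in the
// suffix(r1, o) / prefix(r2rc, o) window; the best-scoring overlap with
// mismatch fraction <= max_mismatch_frac wins, ties going to the longer
// overlap. Consensus takes the higher-quality base at disagreements.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2rc, CharacterVector q2rev,
                     int min_overlap, double max_mismatch_frac) {
  int n = r1.size();
  CharacterVector seq(n), qual(n);
  LogicalVector merged(n);
  IntegerVector overlap(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string qa = as<std::string>(q1[i]);
    std::string b = as<std::string>(r2rc[i]);
    std::string qb = as<std::string>(q2rev[i]);
    int la = a.size(), lb = b.size();
    int best_o = -1, best_match = -1;
    int omax = std::min(la, lb);
    for (int o = min_overlap; o <= omax; ++o) {
      int match = 0;
      const char* pa = a.data() + (la - o);
      const char* pb = b.data();
      for (int j = 0; j < o; ++j)
        if (pa[j] == pb[j]) ++match;
      if ((double)(o - match) / o <= max_mismatch_frac) {
        if (match > best_match || (match == best_match && o > best_o)) {
          best_match = match;
          best_o = o;
        }
      }
    }
    if (best_o < 0) {
      merged[i] = false;
      seq[i] = NA_STRING;
      qual[i] = NA_STRING;
      overlap[i] = 0;
      continue;
    }
    int o = best_o;
    std::string s = a.substr(0, la - o);
    std::string q = qa.substr(0, la - o);
    for (int j = 0; j < o; ++j) {
      char ca = a[la - o + j], cb = b[j];
      char qca = qa[la - o + j], qcb = qb[j];
      if (ca == cb) {
        s.push_back(ca);
        q.push_back(std::max(qca, qcb));
      } else if (qcb > qca) {
        s.push_back(cb);
        q.push_back(qcb);
      } else {
        s.push_back(ca);
        q.push_back(qca);
      }
    }
    s += b.substr(o);
    q += qb.substr(o);
    merged[i] = true;
    seq[i] = s;
    qual[i] = q;
    overlap[i] = o;
  }
  return List::create(_["merged"] = merged, _["seq"] = seq,
                      _["qual"] = qual, _["overlap"] = overlap);
}

// Ungapped reduced-alphabet alignment: reads and reference are supplied
// already C->T collapsed; every offset is scored by match count, ties to the
// leftmost offset. Returns the 0-based best offset (-1 when the read is
// longer than the reference) and its identity.
// [[Rcpp::export]]
List cpp_align_ungapped(CharacterVector reads, std::string ref) {
  int n = reads.size();
  int lr = ref.size();
  IntegerVector offset(n);
  NumericVector identity(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int l = r.size();
    if (l == 0 || l > lr) {
      offset[i] = -1;
      identity[i] = 0.0;
      continue;
    }
    int best_off = 0, best_match = -1;
    for (int off = 0; off + l <= lr; ++off) {
      int match = 0;
      const char* pr = ref.data() + off;
      for (int j = 0; j < l; ++j)
        if (pr[j] == r[j]) ++match;
      if (match > best_match) {
        best_match = match;
        best_off = off;
      }
    }
    offset[i] = best_off;
    identity[i] = (double)best_match / l;
  }
  return List::create(_["offset"] = offset, _["identity"] = identity);
}
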