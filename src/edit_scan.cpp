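// Banded-free infix edit-distance scanning for barcode demultiplexing.
// Levenshtein costs: substitution, insertion, deletion = 1; 'N' (or any
// non-ACGT byte) never matches, so it always costs a substitution.

#include <Rcpp.h>
using namespace Rcpp;

static inline bool base_match(char a, char b) {
  if (a != b) return false;
  switch (a) { case 'A': case 'C': case 'G': case 'T': return true; }
  return false;
}

// Minimum edit distance between `pattern` and any substring of `subject`
// (free start and end in the subject).  `first_end` is the smallest
// 1-based end position whose window achieves that minimum.
static void infix_scan(const std::string& subject, const std::string& pattern,
                       int& best_dist, int& first_end) {
  const int m = pattern.size(), n = subject.size();
  std::vector<int> dp(m + 1), prev(m + 1), ends(n, m);
  for (int i = 0; i <= m; ++i) prev[i] = i;
  best_dist = m;
  first_end = 0;
  for (int j = 1; j <= n; ++j) {
    dp[0] = 0;  // windows may start anywhere
    const char c = subject[j - 1];
    for (int i = 1; i <= m; ++i) {
      int sub = prev[i - 1] + (base_match(pattern[i - 1], c) ? 0 : 1);
      int del = prev[i] + 1;   // skip subject char
      int ins = dp[i - 1] + 1; // skip pattern char
      dp[i] = std::min(sub, std::min(del, ins));
    }
    ends[j - 1] = dp[m];
    if (dp[m] < best_dist) best_dist = dp[m];
    std::swap(dp, prev);
  }
  for (int j = 0; j < n; ++j)
    if (ends[j] == best_dist) { first_end = j + 1; break; }
}

// [[Rcpp::export(name = ".cpp_infix_find")]]
IntegerVector cpp_infix_find(std::string subject, std::string pattern,
                             int max_edits) {
  int best, first_end;
  infix_scan(subject, pattern, best, first_end);
  return IntegerVector::create(_["found"] = best <= max_edits ? 1 : 0,
                               _["end"] = first_end,
                               _["dist"] = best);
}

// [[Rcpp::export(name = ".cpp_infix_dists")]]
IntegerVector cpp_infix_dists(std::string subject, CharacterVector patterns) {
  const int k = patterns.size();
  IntegerVector out(k);
  for (int p = 0; p < k; ++p) {
    int best, first_end;
    infix_scan(subject, std::string(patterns[p]), best, first_end);
    out[p] = best;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int s = 0; s < n; ++s) {
    std::string x(seqs[s]);
    std::string y(x.size(), 'N');
    for (size_t i = 0; i < x.size(); ++i) {
      char c = x[x.size() - 1 - i];
      switch (c) {
        case 'A': y[i] = 'T'; break;
        case 'C': y[i] = 'G'; break;
        case 'G': y[i] = 'C'; break;
        case 'T': y[i] = 'A'; break;
        default: y[i] = 'N';
      }
    }
    out[s] = y;
  }
  return out;
}
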