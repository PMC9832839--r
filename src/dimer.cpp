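#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// Longest common substring between a and b (classic O(nm) DP), plus the
// longest common substring that ends at a's final character.  With
// b = revcomp(other primer), a common substring is exactly an ungapped
// antiparallel complementary run between the two oligos, and a run ending
// at a's final character is a 3'-anchored run of primer a.
static void lcs_runs(const std::string &a, const std::string &b,
                     int &max_run, int &end_run_a) {
  size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  max_run = 0; end_run_a = 0;
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > max_run) max_run = cur[j];
        if (i == n && cur[j] > end_run_a) end_run_a = cur[j];
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
}

// Returns c(max complementary run, run anchored at a's 3' end,
//           run anchored at b's 3' end).
// [[Rcpp::export]]
IntegerVector dimer_stats_cpp(std::string a, std::string b) {
  std::string rcb = revcomp(b), rca = revcomp(a);
  int max_run = 0, run3a = 0, run3b = 0, dummy = 0;
  lcs_runs(a, rcb, max_run, run3a);
  lcs_runs(b, rca, dummy, run3b);
  if (dummy > max_run) max_run = dummy; // symmetric; kept for safety
  return IntegerVector::create(max_run, run3a, run3b);
}

// Vectorized pass/fail over paired primer sequences (recycled pairwise):
// fail when any complementary run >= run_thresh or a 3'-anchored run
// >= end_thresh on either oligo.
// [[Rcpp::export]]
LogicalVector dimer_pass_cpp(CharacterVector a, CharacterVector b,
                             int run_thresh, int end_thresh) {
  int n = std::max(a.size(), b.size());
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    IntegerVector st = dimer_stats_cpp(sa, sb);
    out[i] = !(st[0] >= run_thresh || st[1] >= end_thresh || st[2] >= end_thresh);
  }
  return out;
}
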