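#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Plus-strand k-mer positional index over a set of contigs.  Keys pack the
// 2k-bit k-mer code above a 32-bit global position; one sorted vector gives
// O(log n) range lookup per exact k-mer.  Minus-strand queries are served
// at the R level by looking up the reverse-complement k-mer.
struct KIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<uint64_t> offsets; // global 0-based start of each contig
  std::vector<uint64_t> keys;    // (code << 32) | gpos, sorted
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export]]
SEXP kindex_build_cpp(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 15) stop("k must be between 1 and 15");
  KIndex *idx = new KIndex();
  idx->k = k;
  uint64_t gpos = 0;
  for (int c = 0; c < seqs.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(as<std::string>(seqs[c]));
    idx->offsets.push_back(gpos);
    gpos += idx->seqs.back().size();
  }
  idx->offsets.push_back(gpos); // sentinel
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string &s = idx->seqs[c];
    if ((int)s.size() < k) continue;
    uint64_t code = 0;
    int run = 0; // valid (ACGT-only) bases accumulated
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t start = idx->offsets[c] + i - k + 1;
        idx->keys.push_back((code << 32) | start);
      }
    }
  }
  std::sort(idx->keys.begin(), idx->keys.end());
  XPtr<KIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List kindex_info_cpp(SEXP xp) {
  XPtr<KIndex> idx(xp);
  int n = idx->names.size();
  CharacterVector nm(n);
  NumericVector len(n);
  for (int i = 0; i < n; ++i) {
    nm[i] = idx->names[i];
    len[i] = (double)idx->seqs[i].size();
  }
  return List::create(_["k"] = idx->k, _["contigs"] = nm, _["lengths"] = len,
                      _["n_kmers"] = (double)idx->keys.size());
}

static void query_code(const KIndex *idx, uint64_t code,
                       std::vector<uint64_t> &hits) {
  uint64_t lo = code << 32, hi = (code + 1) << 32;
  auto a = std::lower_bound(idx->keys.begin(), idx->keys.end(), lo);
  auto b = std::lower_bound(idx->keys.begin(), idx->keys.end(), hi);
  for (auto it = a; it != b; ++it) hits.push_back(*it & 0xFFFFFFFFULL);
}

static int gpos_contig(const KIndex *idx, uint64_t gpos) {
  auto it = std::upper_bound(idx->offsets.begin(), idx->offsets.end(), gpos);
  return (int)(it - idx->offsets.begin()) - 1;
}

// Exact plus-strand occurrences of one k-mer; 1-based positions.
// [[Rcpp::export]]
DataFrame kindex_query_cpp(SEXP xp, std::string kmer) {
  XPtr<KIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) stop("query k-mer must be ACGT only");
    code = (code << 2) | (uint64_t)b;
  }
  std::vector<uint64_t> hits;
  query_code(idx, code, hits);
  std::sort(hits.begin(), hits.end());
  int n = hits.size();
  CharacterVector contig(n);
  IntegerVector pos(n);
  for (int i = 0; i < n; ++i) {
    int c = gpos_contig(idx, hits[i]);
    contig[i] = idx->names[c];
    pos[i] = (int)(hits[i] - idx->offsets[c]) + 1;
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// Verify a full-length ungapped alignment of pattern at 0-based start0 of
// contig c.  Mismatches forbidden in the exact zone (first `t` pattern
// positions when exact_at_start, else the last `t`); returns the total
// mismatch count, or -1 when rejected.
static int verify_at(const KIndex *idx, int c, long start0,
                     const std::string &pat, int max_mm, int t,
                     bool exact_at_start) {
  const std::string &s = idx->seqs[c];
  long L = (long)pat.size();
  if (start0 < 0 || start0 + L > (long)s.size()) return -1;
  int mm = 0;
  for (long i = 0; i < L; ++i) {
    if (s[start0 + i] != pat[i]) {
      bool in_exact = exact_at_start ? (i < t) : (i >= L - t);
      if (in_exact) return -1;
      if (++mm > max_mm) return -1;
    }
  }
  return mm;
}

// Enumerate all codes within `budget` substitutions of `code`, restricted to
// seed positions [mut_lo, mut_hi) (0-based within the seed, 5'->3'), and
// collect candidate global positions for each.
static void neighborhood(const KIndex *idx, uint64_t code, int k,
                         int mut_lo, int mut_hi, int budget, int from,
                         std::vector<uint64_t> &hits) {
  query_code(idx, code, hits);
  if (budget == 0) return;
  for (int p = std::max(from, mut_lo); p < mut_hi; ++p) {
    int shift = 2 * (k - 1 - p);
    uint64_t cur = (code >> shift) & 3ULL;
    for (uint64_t nb = 0; nb < 4; ++nb) {
      if (nb == cur) continue;
      uint64_t mut = (code & ~(3ULL << shift)) | (nb << shift);
      neighborhood(idx, mut, k, mut_lo, mut_hi, budget - 1, p + 1, hits);
    }
  }
}

struct Hit { int contig; long start; char strand; int mm; };

static void search_strand(const KIndex *idx, const std::string &pat,
                          int max_mm, int t, bool exact_at_start,
                          char strand, std::vector<Hit> &out) {
  int k = idx->k;
  long L = (long)pat.size();
  // seed sits at the exact-zone end of the pattern
  long seed_off = exact_at_start ? 0 : (L - k);
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(pat[seed_off + i]);
    if (b < 0) stop("primer must be ACGT only");
    code = (code << 2) | (uint64_t)b;
  }
  // positions of the seed where a mismatch is permitted
  int mut_lo = exact_at_start ? t : 0;
  int mut_hi = exact_at_start ? k : (k - t);
  std::vector<uint64_t> cand;
  neighborhood(idx, code, k, mut_lo, mut_hi, max_mm, mut_lo, cand);
  for (uint64_t g : cand) {
    int c = gpos_contig(idx, g);
    long local = (long)(g - idx->offsets[c]);
    long start0 = local - seed_off;
    int mm = verify_at(idx, c, start0, pat, max_mm, t, exact_at_start);
    if (mm >= 0) out.push_back(Hit{c, start0 + 1, strand, mm});
  }
}

// Full-length ungapped primer hits on both strands: <= max_mm mismatches
// overall, none in the 3'-terminal `t` bases.  `start` is the 1-based
// position of the 5'-most matched base on the plus strand.
// [[Rcpp::export]]
DataFrame find_hits_cpp(SEXP xp, std::string primer, int max_mm, int t) {
  XPtr<KIndex> idx(xp);
  long L = (long)primer.size();
  if (L < idx->k + t)
    stop("primer length must be >= k + three_prime_exact");
  std::string rc(primer.rbegin(), primer.rend());
  for (size_t i = 0; i < rc.size(); ++i) rc[i] = comp(rc[i]);
  std::vector<Hit> hits;
  // plus strand: primer as-is, 3' end (exact zone + seed) at pattern end
  search_strand(idx, primer, max_mm, t, false, '+', hits);
  // minus strand: revcomp(primer) on the plus strand; the primer's 3' end
  // maps to the pattern start
  search_strand(idx, rc, max_mm, t, true, '-', hits);
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.start != b.start) return a.start < b.start;
    return a.strand < b.strand;
  });
  int n = hits.size();
  CharacterVector contig(n), strand(n);
  IntegerVector start(n), mm(n);
  for (int i = 0; i < n; ++i) {
    contig[i] = idx->names[hits[i].contig];
    start[i] = (int)hits[i].start;
    strand[i] = std::string(1, hits[i].strand);
    mm[i] = hits[i].mm;
  }
  return DataFrame::create(_["contig"] = contig, _["start"] = start,
                           _["strand"] = strand, _["mismatches"] = mm,
                           _["stringsAsFactors"] = false);
}
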