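#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 2-bit k-mer encoding; k is capped at 31 so a k-mer fits in 64 bits.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// kmer -> (count, first 0-based position); counting saturates at 2 since only
// uniqueness matters.
static void index_kmers(const char *s, size_t n, int k,
                        std::unordered_map<uint64_t, std::pair<int, int> > &map) {
  if (n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int run = 0;  // valid trailing bases
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    size_t pos = i + 1 - k;
    auto it = map.find(h);
    if (it == map.end()) map.emplace(h, std::make_pair(1, (int)pos));
    else if (it->second.first < 2) it->second.first = 2;
  }
}

//' @useDynLib diploscan, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".kmer_anchors")]]
IntegerMatrix kmer_anchors(std::string a, std::string b, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, std::pair<int, int> > ma, mb;
  ma.reserve(a.size() * 2);
  mb.reserve(b.size() * 2);
  index_kmers(a.c_str(), a.size(), k, ma);
  index_kmers(b.c_str(), b.size(), k, mb);
  std::vector<std::pair<int, int> > hits;
  for (auto &kv : ma) {
    if (kv.second.first != 1) continue;
    auto it = mb.find(kv.first);
    if (it == mb.end() || it->second.first != 1) continue;
    hits.push_back(std::make_pair(kv.second.second, it->second.second));
  }
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first;   // 0-based position in a
    out(i, 1) = hits[i].second;  // 0-based position in b
  }
  return out;
}

// Longest strictly-increasing subsequence of y (x assumed strictly increasing,
// i.e. anchors pre-sorted by reference position). Ties resolved toward the
// leftmost chain: patience sorting keeps the smallest tail for each length.
// Returns 1-based indices of the chosen chain.
// [[Rcpp::export(name = ".chain_lis")]]
IntegerVector chain_lis(IntegerVector y) {
  int n = y.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;       // index of smallest tail value per length
  std::vector<int> parent(n, -1);
  tails.reserve(n);
  for (int i = 0; i < n; ++i) {
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {  // first slot whose tail value >= y[i]
      int mid = (lo + hi) / 2;
      if (y[tails[mid]] < y[i]) lo = mid + 1; else hi = mid;
    }
    parent[i] = (lo > 0) ? tails[lo - 1] : -1;
    if (lo == (int)tails.size()) tails.push_back(i);
    else if (y[i] < y[tails[lo]]) tails[lo] = i;
  }
  std::vector<int> chain;
  for (int i = tails.back(); i >= 0; i = parent[i]) chain.push_back(i + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

// Collapse a chained anchor list (strictly increasing in both coordinates)
// into maximal exact-match runs: anchors on the same diagonal that overlap
// or abut extend the current run; an anchor starting inside the previous
// run on either coordinate but on a different diagonal is dropped.
// Input/output positions are 0-based; k is the anchor length.
// Returns a matrix with columns a_start, a_end, b_start, b_end.
// [[Rcpp::export(name = ".collapse_runs")]]
IntegerMatrix collapse_runs(IntegerVector aa, IntegerVector bb, int k) {
  int n = aa.size();
  std::vector<int> ras, eas, rbs, ebs;
  int ra = aa[0], rb = bb[0], ea = aa[0] + k, eb = bb[0] + k;
  for (int t = 1; t < n; ++t) {
    bool same_diag = (aa[t] - bb[t]) == (ra - rb);
    if (same_diag && aa[t] <= ea) {
      ea = aa[t] + k; eb = bb[t] + k;
    } else if (aa[t] >= ea && bb[t] >= eb) {
      ras.push_back(ra); eas.push_back(ea);
      rbs.push_back(rb); ebs.push_back(eb);
      ra = aa[t]; rb = bb[t]; ea = aa[t] + k; eb = bb[t] + k;
    }
    // else: drop the anchor
  }
  ras.push_back(ra); eas.push_back(ea);
  rbs.push_back(rb); ebs.push_back(eb);
  IntegerMatrix out(ras.size(), 4);
  for (size_t i = 0; i < ras.size(); ++i) {
    out(i, 0) = ras[i]; out(i, 1) = eas[i];
    out(i, 2) = rbs[i]; out(i, 3) = ebs[i];
  }
  return out;
}

// Per-base identity of two equal-length strings (mismatch count).
// [[Rcpp::export(name = ".hamming")]]
int hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}
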