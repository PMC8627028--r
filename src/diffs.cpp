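// Reference-vs-query difference counting by exact anchor chaining.
//
// Anchors are k-mers that occur exactly once in each sequence and agree;
// consecutive anchors collapse into maximal exact-match segments, which are
// chained by a match-weighted longest-increasing-subsequence DP. Chained
// segment ends are released by a few bases so the inter-anchor dynamic
// programming can shift the boundary. Between consecutive segments the
// number of matched reference bases is computed exactly by a
// match-maximising (LCS) DP; regions too large for the quadratic DP fall
// back to a banded variant. total_differences = ref_length - matched
// reference bases, i.e. reference bases a 1-to-1 alignment cannot pair with
// an identical query base. Deterministic throughout.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int b2c(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// positions (0-based) of k-mers occurring exactly once; pos = -1 marks repeats
static void unique_kmers(const std::string& s, int k,
                         std::unordered_map<uint64_t, int64_t>& out) {
  const int64_t n = (int64_t)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int64_t i = 0; i < n; ++i) {
    int c = b2c(s[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto it = out.find(key);
      if (it == out.end()) out[key] = i - k + 1;
      else it->second = -1;
    }
  }
}

// exact LCS (number of matched bases); O(len_a * len_b) time, linear memory.
// N (or any non-ACGT) never matches.
static int64_t lcs_full(const char* a, int64_t la, const char* b, int64_t lb) {
  if (la == 0 || lb == 0) return 0;
  std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
  for (int64_t i = 1; i <= la; ++i) {
    int ca = b2c(a[i - 1]);
    for (int64_t j = 1; j <= lb; ++j) {
      int eq = (ca >= 0 && ca == b2c(b[j - 1])) ? 1 : 0;
      int v = prev[j - 1] + eq;
      if (prev[j] > v) v = prev[j];
      if (cur[j - 1] > v) v = cur[j - 1];
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// banded LCS approximation for large regions; band follows the rescaled
// diagonal with half-width w.
static int64_t lcs_banded(const char* a, int64_t la, const char* b, int64_t lb,
                          int64_t w) {
  if (la == 0 || lb == 0) return 0;
  std::vector<int> prev(lb + 2, 0), cur(lb + 2, 0);
  for (int64_t i = 1; i <= la; ++i) {
    int ca = b2c(a[i - 1]);
    int64_t c = (la > 0) ? (i * lb) / la : 0;
    int64_t j0 = std::max((int64_t)1, c - w), j1 = std::min(lb, c + w);
    cur[j0 - 1] = prev[j0 - 1];
    for (int64_t j = j0; j <= j1; ++j) {
      int eq = (ca >= 0 && ca == b2c(b[j - 1])) ? 1 : 0;
      int v = prev[j - 1] + eq;
      if (prev[j] > v) v = prev[j];
      if (cur[j - 1] > v) v = cur[j - 1];
      cur[j] = v;
    }
    for (int64_t j = j1 + 1; j <= lb; ++j) cur[j] = std::max(prev[j], cur[j1]);
    std::swap(prev, cur);
  }
  return prev[lb];
}

static int64_t lcs_dispatch(const char* a, int64_t la, const char* b, int64_t lb,
                            double max_area, int64_t band_extra) {
  if (la == 0 || lb == 0) return 0;
  if ((double)la * (double)lb <= max_area) return lcs_full(a, la, b, lb);
  int64_t w = std::llabs(la - lb) + band_extra;
  return lcs_banded(a, la, b, lb, w);
}

struct Seg { int64_t r, q, len; };

// [[Rcpp::export(name = ".count_differences_cpp")]]
List count_differences_cpp(std::string ref, std::string qry, int k = 21,
                           int trim = 10, double max_dp_area = 4e7,
                           int band_extra = 500) {
  const int64_t lr = (int64_t)ref.size(), lq = (int64_t)qry.size();
  if (lr == 0) stop("empty reference");

  std::unordered_map<uint64_t, int64_t> kr, kq;
  unique_kmers(ref, k, kr);
  unique_kmers(qry, k, kq);

  std::vector<std::pair<int64_t,int64_t>> anchors;  // (rpos, qpos)
  for (auto& kv : kr) {
    if (kv.second < 0) continue;
    auto it = kq.find(kv.first);
    if (it != kq.end() && it->second >= 0)
      anchors.push_back({kv.second, it->second});
  }
  std::sort(anchors.begin(), anchors.end());

  // collapse consecutive anchors into maximal exact-match segments
  std::vector<Seg> segs;
  for (size_t i = 0; i < anchors.size(); ) {
    size_t j = i + 1;
    while (j < anchors.size() &&
           anchors[j].first == anchors[j - 1].first + 1 &&
           anchors[j].second == anchors[j - 1].second + 1) ++j;
    Seg s; s.r = anchors[i].first; s.q = anchors[i].second;
    s.len = (anchors[j - 1].first - anchors[i].first) + k;
    segs.push_back(s);
    i = j;
  }

  int64_t matched = 0;
  bool no_anchors = segs.empty();

  if (no_anchors) {
    if ((double)lr * (double)lq <= max_dp_area) {
      matched = lcs_full(ref.c_str(), lr, qry.c_str(), lq);
    } else {
      matched = 0;  // fully diverged fallback; caller warns
    }
  } else {
    // chain by weighted LIS: both coordinates strictly increasing, no overlap
    const size_t m = segs.size();
    std::vector<int64_t> score(m);
    std::vector<int64_t> parent(m, -1);
    int64_t best = -1; size_t besti = 0;
    for (size_t i = 0; i < m; ++i) {
      score[i] = segs[i].len;
      for (size_t j = 0; j < i; ++j) {
        if (segs[j].r + segs[j].len <= segs[i].r &&
            segs[j].q + segs[j].len <= segs[i].q) {
          int64_t s = score[j] + segs[i].len;
          if (s > score[i]) { score[i] = s; parent[i] = (int64_t)j; }
        }
      }
      if (score[i] > best) { best = score[i]; besti = i; }
    }
    std::vector<Seg> chain;
    for (int64_t i = (int64_t)besti; i >= 0; i = parent[i]) chain.push_back(segs[i]);
    std::reverse(chain.begin(), chain.end());

    // release segment ends so boundary bases can be re-aligned in the gaps
    for (auto& s : chain) {
      int64_t t = std::min((int64_t)trim, (s.len - 1) / 2);
      s.r += t; s.q += t; s.len -= 2 * t;
    }

    int64_t pr = 0, pq = 0;
    for (auto& s : chain) {
      matched += lcs_dispatch(ref.c_str() + pr, s.r - pr,
                              qry.c_str() + pq, s.q - pq,
                              max_dp_area, band_extra);
      matched += s.len;
      pr = s.r + s.len; pq = s.q + s.len;
    }
    matched += lcs_dispatch(ref.c_str() + pr, lr - pr,
                            qry.c_str() + pq, lq - pq,
                            max_dp_area, band_extra);
  }

  if (matched > lr) matched = lr;
  return List::create(_["ref_length"] = (double)lr,
                      _["matched"] = (double)matched,
                      _["total_differences"] = (double)(lr - matched),
                      _["n_segments"] = (double)segs.size(),
                      _["no_anchors"] = no_anchors);
}
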