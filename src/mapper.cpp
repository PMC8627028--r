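// Seed-and-extend paired-read mapper.
//
// Index: exact k-mer hash over the target sequences (k <= 31, 2-bit packed);
// k-mers occurring more than max_occ times are treated as repetitive and
// skipped at lookup time. Per read, seeds are taken every `stride` bases on
// both strands; seed hits vote for (target, diagonal) candidates, the top
// candidates are evaluated by ungapped extension, and the best-scoring
// maximal segment (linear gain for a match, `mismatch_penalty` loss for a
// mismatch) defines the aligned interval; bases outside it are soft-clipped.
// Tie-breaking is fully deterministic: (matches desc, mismatches asc,
// target index, position, strand).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct KmerIndex {
  int k;
  int max_occ;
  // kmer -> list of (tid, pos) encoded as int64: tid << 40 | pos
  std::unordered_map<uint64_t, std::vector<int64_t>> map;
};

static void index_sequence(KmerIndex& idx, const std::string& seq, int tid) {
  const int k = idx.k;
  const int64_t n = (int64_t)seq.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int64_t i = 0; i < n; ++i) {
    int c = base2code(seq[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto& v = idx.map[key];
      if ((int)v.size() <= idx.max_occ)  // cap; overflow marks repeat
        v.push_back(((int64_t)tid << 40) | (i - k + 1));
    }
  }
}

struct Hit {
  int tid;
  int64_t start;     // proposed read start on target (may be negative)
  int votes;
};

struct Aln {
  bool ok = false;
  int tid = -1;
  int64_t tstart = 0, tend = 0;  // aligned interval on target, 0-based half-open
  int qstart = 0, qend = 0;      // aligned interval on (oriented) read
  int matches = 0, mismatches = 0;
  bool rev = false;
  std::vector<int> mm_tpos;      // target positions of mismatches inside segment
};

// Ungapped evaluation of read placed at target offset `start`; returns the
// maximal-scoring contiguous segment (Kadane) with per-base bookkeeping.
static Aln evaluate(const std::string& tgt, const std::string& read,
                    int tid, int64_t start, bool rev, int mismatch_penalty) {
  Aln a;
  const int64_t L = (int64_t)tgt.size();
  const int rl = (int)read.size();
  int64_t lo = std::max((int64_t)0, start);
  int64_t hi = std::min(L, start + rl);
  if (hi <= lo) return a;

  long best = 0, cur = 0;
  int cur_q0 = (int)(lo - start);
  int best_q0 = 0, best_q1 = 0;
  for (int64_t t = lo; t < hi; ++t) {
    int q = (int)(t - start);
    bool m = false;
    int ct = base2code(tgt[t]), cr = base2code(read[q]);
    if (ct >= 0 && cr >= 0 && ct == cr) m = true;
    long gain = m ? 1 : -(long)mismatch_penalty;
    if (cur <= 0) { cur = gain; cur_q0 = q; }
    else cur += gain;
    if (cur > best) { best = cur; best_q0 = cur_q0; best_q1 = q + 1; }
  }
  if (best <= 0) return a;

  a.ok = true; a.tid = tid; a.rev = rev;
  a.qstart = best_q0; a.qend = best_q1;
  a.tstart = start + best_q0; a.tend = start + best_q1;
  for (int q = best_q0; q < best_q1; ++q) {
    int64_t t = start + q;
    int ct = base2code(tgt[t]), cr = base2code(read[q]);
    if (ct >= 0 && cr >= 0 && ct == cr) a.matches++;
    else { a.mismatches++; a.mm_tpos.push_back((int)t); }
  }
  return a;
}

static bool better(const Aln& x, const Aln& y) {
  // true if x strictly better than y under the deterministic order
  if (x.matches != y.matches) return x.matches > y.matches;
  if (x.mismatches != y.mismatches) return x.mismatches < y.mismatches;
  if (x.tid != y.tid) return x.tid < y.tid;
  if (x.tstart != y.tstart) return x.tstart < y.tstart;
  return !x.rev && y.rev;
}

// Map one oriented read; returns best alignment over both strands.
static Aln map_one(const KmerIndex& idx,
                   const std::vector<std::string>& targets,
                   const std::string& read, int stride, int max_candidates,
                   int mismatch_penalty) {
  const int k = idx.k;
  const int rl = (int)read.size();
  Aln best;
  for (int strand = 0; strand < 2; ++strand) {
    std::string r = strand ? revcomp(read) : read;
    if (rl < k) continue;
    // collect votes per (tid, diagonal)
    std::unordered_map<int64_t, int> votes;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int o = 0; o + k <= rl; o += stride) {
      uint64_t key = 0; bool okk = true;
      for (int j = 0; j < k; ++j) {
        int c = base2code(r[o + j]);
        if (c < 0) { okk = false; break; }
        key = ((key << 2) | (uint64_t)c) & mask;
      }
      if (!okk) continue;
      auto it = idx.map.find(key);
      if (it == idx.map.end()) continue;
      if ((int)it->second.size() > idx.max_occ) continue;  // repetitive
      for (int64_t enc : it->second) {
        int tid = (int)(enc >> 40);
        int64_t pos = enc & ((1LL << 40) - 1);
        int64_t diag = pos - o;  // proposed read start on target
        votes[((int64_t)tid << 41) ^ (diag + (1LL << 40))]++;
        (void)diag;
      }
    }
    if (votes.empty()) continue;
    std::vector<std::pair<int64_t,int>> cand(votes.begin(), votes.end());
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<int64_t,int>& a, const std::pair<int64_t,int>& b) {
                if (a.second != b.second) return a.second > b.second;
                return a.first < b.first;
              });
    int ncand = std::min((int)cand.size(), max_candidates);
    for (int i = 0; i < ncand; ++i) {
      int tid = (int)(cand[i].first >> 41);
      int64_t diag = ((cand[i].first ^ ((int64_t)tid << 41))) - (1LL << 40);
      Aln a = evaluate(targets[tid], r, tid, diag, strand == 1, mismatch_penalty);
      if (a.ok && (!best.ok || better(a, best))) best = a;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector target_seqs, CharacterVector read1,
                   CharacterVector read2, int k = 17, int stride = 8,
                   double min_identity = 0.5, int mismatch_penalty = 3,
                   int max_candidates = 4, int max_occ = 64) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  const int nt = target_seqs.size();
  std::vector<std::string> targets(nt);
  for (int i = 0; i < nt; ++i) targets[i] = as<std::string>(target_seqs[i]);

  KmerIndex idx; idx.k = k; idx.max_occ = max_occ;
  for (int i = 0; i < nt; ++i) index_sequence(idx, targets[i], i);

  const int np = read1.size();
  if (read2.size() != np) stop("read1 and read2 must have equal length");

  // per-target tracks
  std::vector<std::vector<int>> read_depth(nt), perfect_depth(nt);
  for (int i = 0; i < nt; ++i) {
    read_depth[i].assign(targets[i].size(), 0);
    perfect_depth[i].assign(targets[i].size(), 0);
  }

  std::vector<int> o_pair, o_mate, o_tid;
  std::vector<double> o_start, o_end;
  std::vector<int> o_strand, o_clipl, o_clipr, o_match, o_mismatch;
  std::vector<double> o_identity;

  for (int p = 0; p < np; ++p) {
    for (int mate = 1; mate <= 2; ++mate) {
      std::string rd = as<std::string>(mate == 1 ? read1[p] : read2[p]);
      int rl = (int)rd.size();
      if (rl == 0) continue;
      Aln a = map_one(idx, targets, rd, stride, max_candidates, mismatch_penalty);
      if (!a.ok) continue;
      double ident = (double)a.matches / (double)rl;
      if (ident < min_identity) continue;
      int clipl = a.qstart, clipr = rl - a.qend;
      o_pair.push_back(p + 1); o_mate.push_back(mate); o_tid.push_back(a.tid + 1);
      o_start.push_back((double)a.tstart); o_end.push_back((double)a.tend);
      o_strand.push_back(a.rev ? -1 : 1);
      o_clipl.push_back(clipl); o_clipr.push_back(clipr);
      o_match.push_back(a.matches); o_mismatch.push_back(a.mismatches);
      o_identity.push_back(ident);
      // depth tracks
      auto& rdv = read_depth[a.tid];
      for (int64_t t = a.tstart; t < a.tend; ++t) rdv[t]++;
      if (clipl == 0 && clipr == 0) {
        auto& pf = perfect_depth[a.tid];
        for (int64_t t = a.tstart; t < a.tend; ++t) pf[t]++;
        for (int mm : a.mm_tpos) pf[mm]--;  // mismatched bases do not count
      }
    }
  }

  DataFrame aln = DataFrame::create(
    _["pair"] = o_pair, _["mate"] = o_mate, _["tid"] = o_tid,
    _["start"] = o_start, _["end"] = o_end, _["strand"] = o_strand,
    _["clip_left"] = o_clipl, _["clip_right"] = o_clipr,
    _["matches"] = o_match, _["mismatches"] = o_mismatch,
    _["identity"] = o_identity);

  List rdl(nt), pfl(nt);
  for (int i = 0; i < nt; ++i) {
    rdl[i] = IntegerVector(read_depth[i].begin(), read_depth[i].end());
    pfl[i] = IntegerVector(perfect_depth[i].begin(), perfect_depth[i].end());
  }
  return List::create(_["alignments"] = aln, _["read_depth"] = rdl,
                      _["perfect_depth"] = pfl);
}
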