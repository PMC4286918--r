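#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding of A/C/G/T; -1 for anything else
static inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export]]
int cpp_hamming(std::string p, std::string q) {
  if (p.size() != q.size()) stop("length mismatch");
  int d = 0;
  for (size_t i = 0; i < p.size(); ++i) if (p[i] != q[i]) ++d;
  return d;
}

static void encodeAll(const CharacterVector& v, int l,
                      std::vector<uint8_t>& out, const char* what) {
  const int n = v.size();
  out.resize((size_t)n * l);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(v, i));
    for (int j = 0; j < l; ++j) {
      if (s[j] == '\0') stop("%s pattern %d shorter than l", what, i + 1);
      int c = baseCode(s[j]);
      if (c < 0) stop("%s pattern %d has a non-ACGT character", what, i + 1);
      out[(size_t)i * l + j] = (uint8_t)c;
    }
    if (s[l] != '\0') stop("%s pattern %d longer than l", what, i + 1);
  }
}

// pack segment [off, off+len) of pattern p into a 2-bit code
static inline uint64_t segCode(const uint8_t* p, int off, int len) {
  uint64_t code = 0;
  for (int j = 0; j < len; ++j) code = (code << 2) | p[off + j];
  return code;
}

typedef std::unordered_map<uint64_t, std::vector<int> > CandIndex;

struct SrcMember { int idx; int dist; };

// enumerate all codes within Hamming distance <= budget of the segment of q
// starting at off with length len; call f(code, dist) for each
template <typename F>
static void enumBall(const uint8_t* q, int off, int len, int budget, F f) {
  // DFS over substitution positions (strictly increasing) to avoid dupes
  struct Rec {
    const uint8_t* q; int off; int len; F& f;
    void go(uint64_t code, int fromPos, int distUsed, int budget) {
      f(code, distUsed);
      if (distUsed == budget) return;
      for (int p = fromPos; p < len; ++p) {
        int shift = 2 * (len - 1 - p);
        uint64_t cleared = code & ~((uint64_t)3 << shift);
        int orig = q[off + p];
        for (int b = 0; b < 4; ++b) {
          if (b == orig) continue;
          // recurse with substitution at p; further subs only at later pos
          Rec{q, off, len, f}.go(cleared | ((uint64_t)b << shift),
                                 p + 1, distUsed + 1, budget);
        }
      }
    }
  };
  uint64_t base = segCode(q, off, len);
  Rec{q, off, len, f}.go(base, 0, 0, budget);
}

// Segment-group filtered discovery: returns the 1-based positions of the
// candidates with no (l,d)-similar source occurrence, plus counters.
// seg_len / seg_budget describe the segmentation scheme; chunk_budget is the
// number of source patterns ingested per chunk; workers partitions each
// chunk's group list into interleaved slices (output-invariant; affects only
// the granularity at which immediate candidate purging propagates).
// [[Rcpp::export]]
List cpp_discover(CharacterVector cand, CharacterVector src,
                  IntegerVector cand_ids, IntegerVector src_ids,
                  int l, int d, IntegerVector seg_len,
                  IntegerVector seg_budget, double chunk_budget,
                  int workers, bool self_skip) {
  const int m = cand.size(), n = src.size(), beta = seg_len.size();
  if (cand_ids.size() != m || src_ids.size() != n)
    stop("occurrence id vectors must parallel the pattern vectors");
  for (int i = 0; i < beta; ++i)
    if (seg_len[i] > 28) stop("fast engine requires segment length <= 28");

  std::vector<uint8_t> C, S;
  encodeAll(cand, l, C, "candidate");
  encodeAll(src, l, S, "source");

  std::vector<int> segOff(beta);
  for (int i = 0, o = 0; i < beta; ++i) { segOff[i] = o; o += seg_len[i]; }

  // candidate index: key -> candidate positions (exact segment match)
  CandIndex index;
  for (int c = 0; c < m; ++c)
    for (int i = 0; i < beta; ++i) {
      uint64_t key = (segCode(&C[(size_t)c * l], segOff[i], seg_len[i]) << 6)
                     | (uint64_t)i;
      index[key].push_back(c);
    }
  const double indexKeys = (double)index.size();

  std::vector<char> alive(m, 1);
  double strCmp = 0, chrCmp = 0, groupsProcessed = 0;

  const int chunkSize = (chunk_budget >= n || !R_finite(chunk_budget))
                          ? (n > 0 ? n : 1) : (int)chunk_budget;

  for (int lo = 0; lo < n; lo += chunkSize) {
    const int hi = std::min(n, lo + chunkSize);
    // assign chunk members to the groups present in the candidate index
    std::unordered_map<uint64_t, std::vector<SrcMember> > srcGroups;
    for (int s = lo; s < hi; ++s) {
      const uint8_t* qs = &S[(size_t)s * l];
      for (int i = 0; i < beta; ++i) {
        enumBall(qs, segOff[i], seg_len[i], seg_budget[i],
                 [&](uint64_t code, int dist) {
                   uint64_t key = (code << 6) | (uint64_t)i;
                   if (index.count(key))
                     srcGroups[key].push_back(SrcMember{s, dist});
                 });
      }
    }
    // deterministic group order, then interleaved worker slices
    std::vector<uint64_t> keys;
    keys.reserve(srcGroups.size());
    for (auto& kv : srcGroups) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    const int nw = std::max(1, workers);
    for (int w = 0; w < nw; ++w) {
      for (size_t k = w; k < keys.size(); k += nw) {
        const uint64_t key = keys[k];
        const int segIdx = (int)(key & 63);
        const int off = segOff[segIdx], len = seg_len[segIdx];
        const std::vector<SrcMember>& members = srcGroups[key];
        for (int c : index[key]) {
          if (!alive[c]) continue;
          const uint8_t* pc = &C[(size_t)c * l];
          for (const SrcMember& sm : members) {
            if (self_skip && cand_ids[c] == src_ids[sm.idx]) continue;
            strCmp += 1;
            // the candidate's segment equals the key exactly, so the
            // mismatches inside it equal the member's known distance to
            // the key; only the other l - len positions are compared
            int mism = sm.dist;
            const uint8_t* qs = &S[(size_t)sm.idx * l];
            for (int j = 0; j < l && mism <= d; ++j) {
              if (j >= off && j < off + len) continue;
              chrCmp += 1;
              if (pc[j] != qs[j]) ++mism;
            }
            if (mism <= d) { alive[c] = 0; break; }
          }
          if (!alive[c]) continue;
        }
        groupsProcessed += 1;
      }
    }
  }

  std::vector<int> uniq;
  for (int c = 0; c < m; ++c) if (alive[c]) uniq.push_back(c + 1);
  return List::create(
    _["unique"] = wrap(uniq),
    _["string_comparisons"] = strCmp,
    _["character_comparisons"] = chrCmp,
    _["groups_processed"] = groupsProcessed,
    _["index_keys"] = indexKeys);
}

// Independent all-pairs oracle: no segment filtering, plain Hamming scan
// with early exit. Returns 1-based positions of unique candidates.
// [[Rcpp::export]]
IntegerVector cpp_brute_unique(CharacterVector cand, CharacterVector src,
                               IntegerVector cand_ids, IntegerVector src_ids,
                               int l, int d, bool self_skip) {
  const int m = cand.size(), n = src.size();
  std::vector<uint8_t> C, S;
  encodeAll(cand, l, C, "candidate");
  encodeAll(src, l, S, "source");
  std::vector<int> uniq;
  for (int c = 0; c < m; ++c) {
    const uint8_t* pc = &C[(size_t)c * l];
    bool isUnique = true;
    for (int s = 0; s < n && isUnique; ++s) {
      if (self_skip && cand_ids[c] == src_ids[s]) continue;
      const uint8_t* qs = &S[(size_t)s * l];
      int mism = 0;
      for (int j = 0; j < l; ++j) {
        if (pc[j] != qs[j] && ++mism > d) break;
      }
      if (mism <= d) isUnique = false;
    }
    if (isUnique) uniq.push_back(c + 1);
  }
  return wrap(uniq);
}
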