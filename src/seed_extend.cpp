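#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Ungapped seed-and-extend aligner for short nucleotide queries.
//
// Targets are indexed by exact k-mers (forward strand only); queries are
// searched on both strands by reverse-complementing the query.  Every seeded
// (target, diagonal, strand) triple is extended to the maximal-scoring
// ungapped local alignment on that diagonal (Kadane scan), so at most one
// hit is reported per triple.  Windows containing non-ACGT characters never
// seed and always score as mismatches.

static inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string revcompStr(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default:  r[i] = 'N'; break;
    }
  }
  return r;
}

// sorted (kmer, target<<32|offset) postings; offsets 0-based
struct SeedDb {
  std::vector<std::pair<uint64_t, uint64_t> > post;
  int k;

  void build(const std::vector<std::string> &targets, int k_) {
    k = k_;
    uint64_t mask = (static_cast<uint64_t>(1) << (2 * k)) - 1;
    for (size_t t = 0; t < targets.size(); ++t) {
      const std::string &s = targets[t];
      if (static_cast<int>(s.size()) < k) continue;
      uint64_t kmer = 0;
      int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = baseCode(s[i]);
        if (c < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | static_cast<uint64_t>(c)) & mask;
        if (++valid >= k)
          post.push_back(std::make_pair(
              kmer, (static_cast<uint64_t>(t) << 32) |
                        static_cast<uint64_t>(i - k + 1)));
      }
    }
    std::sort(post.begin(), post.end());
  }
};

struct RawHit {
  int qidx;
  int tidx;
  char strand;
  int qs, qe, ts, te;     // 1-based, qs/qe in original query coordinates
  int identities, alnLen, longestRun;
  double score;
};

// maximal-scoring interval on one diagonal; first strictly-better interval
// wins (deterministic; mirrored by the exhaustive oracle used in tests)
static bool kadaneDiagonal(const std::string &q, const std::string &t,
                           int diag, double match, double mismatch,
                           int &bs, int &be, double &bestScore) {
  int qlen = static_cast<int>(q.size());
  int tlen = static_cast<int>(t.size());
  int lo = std::max(0, -diag);
  int hi = std::min(qlen, tlen - diag); // exclusive
  if (lo >= hi) return false;
  double cur = 0.0, best = 0.0;
  int curStart = lo;
  bs = be = -1;
  for (int i = lo; i < hi; ++i) {
    int qc = baseCode(q[i]);
    int tc = baseCode(t[i + diag]);
    bool m = (qc >= 0) && (qc == tc);
    cur += m ? match : mismatch;
    if (cur > best) { best = cur; bs = curStart; be = i; }
    if (cur < 0) { cur = 0.0; curStart = i + 1; }
  }
  if (bs < 0 || best <= 0.0) return false;
  bestScore = best;
  return true;
}

static void intervalStats(const std::string &q, const std::string &t,
                          int diag, int bs, int be, int &identities,
                          int &longestRun) {
  identities = 0;
  longestRun = 0;
  int run = 0;
  for (int i = bs; i <= be; ++i) {
    int qc = baseCode(q[i]);
    bool m = (qc >= 0) && (qc == baseCode(t[i + diag]));
    if (m) {
      ++identities;
      if (++run > longestRun) longestRun = run;
    } else {
      run = 0;
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector query, CharacterVector query_id,
                          CharacterVector target, CharacterVector target_id,
                          int k, double match, double mismatch,
                          bool both_strands = true) {
  if (k < 1 || k > 31) stop("word size k must be in [1, 31]");
  std::vector<std::string> tg(target.size());
  for (R_xlen_t i = 0; i < target.size(); ++i) tg[i] = as<std::string>(target[i]);

  SeedDb db;
  db.build(tg, k);
  uint64_t mask = (static_cast<uint64_t>(1) << (2 * k)) - 1;

  std::vector<int> qlens(query.size());
  std::vector<RawHit> hits;
  for (R_xlen_t qi = 0; qi < query.size(); ++qi) {
    std::string qfwd = as<std::string>(query[qi]);
    int qlen = static_cast<int>(qfwd.size());
    qlens[qi] = qlen;
    int nStrands = both_strands ? 2 : 1;
    for (int si = 0; si < nStrands; ++si) {
      char strand = (si == 0) ? '+' : '-';
      std::string qs = (si == 0) ? qfwd : revcompStr(qfwd);
      if (qlen < k) continue;

      // seeded (target, diagonal) candidates
      std::vector<std::pair<int, int> > cands;
      uint64_t kmer = 0;
      int valid = 0;
      for (int i = 0; i < qlen; ++i) {
        int c = baseCode(qs[i]);
        if (c < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | static_cast<uint64_t>(c)) & mask;
        if (++valid >= k) {
          int qpos = i - k + 1;
          std::pair<uint64_t, uint64_t> lo(kmer, 0);
          std::pair<uint64_t, uint64_t> hi(kmer, ~static_cast<uint64_t>(0));
          std::vector<std::pair<uint64_t, uint64_t> >::const_iterator it =
              std::lower_bound(db.post.begin(), db.post.end(), lo);
          std::vector<std::pair<uint64_t, uint64_t> >::const_iterator en =
              std::upper_bound(db.post.begin(), db.post.end(), hi);
          for (; it != en; ++it) {
            int tid = static_cast<int>(it->second >> 32);
            int tpos = static_cast<int>(it->second & 0xffffffffu);
            cands.push_back(std::make_pair(tid, tpos - qpos));
          }
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

      for (size_t ci = 0; ci < cands.size(); ++ci) {
        int tid = cands[ci].first;
        int diag = cands[ci].second;
        int bs, be;
        double score;
        if (!kadaneDiagonal(qs, tg[tid], diag, match, mismatch, bs, be, score))
          continue;
        RawHit h;
        h.qidx = static_cast<int>(qi);
        h.tidx = tid;
        h.strand = strand;
        h.ts = bs + diag + 1;
        h.te = be + diag + 1;
        if (strand == '+') {
          h.qs = bs + 1;
          h.qe = be + 1;
        } else { // map back to original query coordinates
          h.qs = qlen - (be + 1) + 1;
          h.qe = qlen - (bs + 1) + 1;
        }
        h.alnLen = be - bs + 1;
        intervalStats(qs, tg[tid], diag, bs, be, h.identities, h.longestRun);
        h.score = score;
        hits.push_back(h);
      }
    }
  }

  R_xlen_t n = static_cast<R_xlen_t>(hits.size());
  CharacterVector oq(n), ot(n), ost(n);
  IntegerVector qs(n), qe(n), ts(n), te(n), idn(n), aln(n), run(n), qln(n);
  NumericVector sc(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const RawHit &h = hits[i];
    oq[i] = query_id[h.qidx];
    ot[i] = target_id[h.tidx];
    ost[i] = std::string(1, h.strand);
    qs[i] = h.qs; qe[i] = h.qe; ts[i] = h.ts; te[i] = h.te;
    idn[i] = h.identities; aln[i] = h.alnLen; run[i] = h.longestRun;
    qln[i] = qlens[h.qidx];
    sc[i] = h.score;
  }
  return DataFrame::create(
      _["query_id"] = oq, _["target_id"] = ot, _["strand"] = ost,
      _["q_start"] = qs, _["q_end"] = qe, _["t_start"] = ts, _["t_end"] = te,
      _["q_len"] = qln, _["identities"] = idn, _["aln_length"] = aln,
      _["longest_contiguous"] = run, _["raw_score"] = sc,
      _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
double cpp_n_postings(CharacterVector target, int k) {
  if (k < 1 || k > 31) stop("word size k must be in [1, 31]");
  std::vector<std::string> tg(target.size());
  for (R_xlen_t i = 0; i < target.size(); ++i) tg[i] = as<std::string>(target[i]);
  SeedDb db;
  db.build(tg, k);
  return static_cast<double>(db.post.size());
}
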