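// Local alignment of short fixed-length reads against contigs under the
// +1/-1 match/mismatch, linear gap-cost scheme (open = extend), plus a full
// Smith-Waterman oracle used for verification. The seeded path and the
// oracle are deliberately separate code paths: the oracle always scans the
// full dynamic-programming matrix, the seeded path only windows around
// shared words.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

inline int bidx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

std::string revcomp1(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default:  c = 'N';
    }
  }
  return r;
}

bool encode(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = bidx(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

struct Aln {
  int cstart, cend, rstart, rend;  // 0-based half-open
  int score, nmatch, nmm, ngap;
  int strand;  // 0 = '+', 1 = '-'
};

// Best local alignment of q against c[ws, we) with linear gap cost.
// `blocked`, if given, has length we-ws; blocked columns are forced to 0.
// Ties resolved toward the smallest (i, j) end cell, so results are
// deterministic.
bool sw_best(const std::string& q, const std::string& c, int ws, int we,
             int match, int mismatch, int gap,
             const std::vector<char>* blocked, Aln& out) {
  int m = (int)q.size(), w = we - ws;
  if (w <= 0 || m <= 0) return false;
  size_t W = (size_t)w + 1;
  // scratch matrices are reused across calls; rows are rewritten in full
  static std::vector<int> H;
  static std::vector<unsigned char> tb;
  size_t need = (size_t)(m + 1) * W;
  if (H.size() < need) { H.resize(need); tb.resize(need); }
  std::fill(H.begin(), H.begin() + W, 0);
  std::fill(tb.begin(), tb.begin() + W, 0);
  for (int i = 0; i <= m; ++i) { H[(size_t)i * W] = 0; tb[(size_t)i * W] = 0; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int qb = bidx(q[i - 1]);
    size_t ro = (size_t)i * W, po = (size_t)(i - 1) * W;
    for (int j = 1; j <= w; ++j) {
      if (blocked && (*blocked)[j - 1]) { H[ro + j] = 0; tb[ro + j] = 0; continue; }
      int cb = bidx(c[ws + j - 1]);
      int sub = (qb >= 0 && qb == cb) ? match : mismatch;
      int v = H[po + j - 1] + sub;
      unsigned char t = 1;
      int u = H[po + j] - gap;
      if (u > v) { v = u; t = 2; }
      int l = H[ro + j - 1] - gap;
      if (l > v) { v = l; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      H[ro + j] = v; tb[ro + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  int i = bi, j = bj, nm = 0, nmm = 0, ng = 0;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * W + j];
    if (t == 0) break;
    if (t == 1) {
      if (bidx(q[i - 1]) >= 0 && bidx(q[i - 1]) == bidx(c[ws + j - 1])) ++nm; else ++nmm;
      --i; --j;
    } else if (t == 2) { ++ng; --i; }
    else { ++ng; --j; }
  }
  out.rstart = i; out.rend = bi;
  out.cstart = ws + j; out.cend = ws + bj;
  out.score = best; out.nmatch = nm; out.nmm = nmm; out.ngap = ng;
  return true;
}

inline bool passes(const Aln& a, bool score_mode, int min_score,
                   double min_identity, int min_len) {
  if (score_mode) return a.score >= min_score;
  int cols = a.nmatch + a.nmm + a.ngap;
  if (cols < min_len) return false;
  return (double)a.nmatch / (double)cols >= min_identity;
}

// lowest score any alignment passing the identity filter can have,
// assuming no gap columns (the substitution-only regime this package
// simulates); used as the iteration floor when extracting multiple hits
inline int score_floor(bool score_mode, int min_score, double min_identity,
                       int min_len) {
  if (score_mode) return min_score;
  double f = (2.0 * min_identity - 1.0) * (double)min_len;
  int fl = (int)std::ceil(f - 1e-9);
  return std::max(fl, 1);
}

// order candidate hits: higher score first, then leftmost, then '+' strand
bool cand_lt(const Aln& a, const Aln& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.cstart != b.cstart) return a.cstart < b.cstart;
  if (a.strand != b.strand) return a.strand < b.strand;
  return a.cend < b.cend;
}

DataFrame hits_frame(std::vector<Aln>& hits, std::vector<int>& ridx) {
  int n = (int)hits.size();
  // sort by contig_start, then read index
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (hits[a].cstart != hits[b].cstart) return hits[a].cstart < hits[b].cstart;
    if (ridx[a] != ridx[b]) return ridx[a] < ridx[b];
    return hits[a].strand < hits[b].strand;
  });
  IntegerVector ri(n), cs(n), ce(n), rs(n), re(n), sc(n), nm(n), nmm(n), ng(n);
  CharacterVector st(n);
  NumericVector id(n);
  for (int o = 0; o < n; ++o) {
    const Aln& a = hits[ord[o]];
    ri[o] = ridx[ord[o]]; cs[o] = a.cstart; ce[o] = a.cend;
    rs[o] = a.rstart; re[o] = a.rend; sc[o] = a.score;
    nm[o] = a.nmatch; nmm[o] = a.nmm; ng[o] = a.ngap;
    st[o] = a.strand == 0 ? "+" : "-";
    int cols = a.nmatch + a.nmm + a.ngap;
    id[o] = cols > 0 ? (double)a.nmatch / cols : 0.0;
  }
  return DataFrame::create(
      _["read_index"] = ri, _["contig_start"] = cs, _["contig_end"] = ce,
      _["read_start"] = rs, _["read_end"] = re, _["strand"] = st,
      _["score"] = sc, _["n_match"] = nm, _["n_mismatch"] = nmm,
      _["n_gap"] = ng, _["identity"] = id,
      _["stringsAsFactors"] = false);
}

}  // namespace

// Seed-and-extend alignment of a read pool against one contig.
// min_score == NA -> identity mode (min_identity + min_len filter).
// [[Rcpp::export]]
DataFrame align_reads_cpp(CharacterVector reads, std::string contig,
                          int word_size, int match, int mismatch, int gap,
                          double min_identity, int min_score, int min_len,
                          int band) {
  bool score_mode = (min_score != NA_INTEGER);
  int floor_sc = score_floor(score_mode, min_score, min_identity, min_len);
  int clen = (int)contig.size();
  std::unordered_map<uint64_t, std::vector<int>> idx;
  if (clen >= word_size) {
    idx.reserve((size_t)clen + 16);
    for (int p = 0; p + word_size <= clen; ++p) {
      uint64_t v;
      if (encode(contig.c_str() + p, word_size, v)) idx[v].push_back(p);
    }
  }
  std::vector<Aln> out_hits;
  std::vector<int> out_ridx;
  int nreads = reads.size();
  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::vector<Aln> cand;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fwd : revcomp1(fwd);
      int m = (int)q.size();
      if (m < word_size) continue;
      // seed windows implied by shared words: [diag - band, diag + m + band)
      std::vector<std::pair<int, int>> win;  // candidate [ws, we)
      for (int i = 0; i + word_size <= m; ++i) {
        uint64_t v;
        if (!encode(q.c_str() + i, word_size, v)) continue;
        auto it = idx.find(v);
        if (it == idx.end()) continue;
        for (int cp : it->second) {
          int d = cp - i;
          win.push_back({std::max(0, d - band),
                         std::min(clen, d + m + band)});
        }
      }
      if (win.empty()) continue;
      std::sort(win.begin(), win.end());
      // merge overlapping windows
      std::vector<std::pair<int, int>> merged;
      for (auto& wv : win) {
        if (!merged.empty() && wv.first <= merged.back().second)
          merged.back().second = std::max(merged.back().second, wv.second);
        else
          merged.push_back(wv);
      }
      for (auto& wv : merged) {
        int ws = wv.first, we = wv.second;
        std::vector<char> blocked(we - ws, 0);
        for (int iter = 0; iter < 64; ++iter) {
          Aln a;
          if (!sw_best(q, contig, ws, we, match, mismatch, gap, &blocked, a))
            break;
          if (a.score < floor_sc) break;
          a.strand = strand;
          if (strand == 1) {  // report read coords on the original read
            int rs = m - a.rend, re = m - a.rstart;
            a.rstart = rs; a.rend = re;
          }
          if (passes(a, score_mode, min_score, min_identity, min_len))
            cand.push_back(a);
          for (int p = a.cstart; p < a.cend; ++p) blocked[p - ws] = 1;
        }
      }
    }
    if (cand.empty()) continue;
    // dedupe identical alignments found through overlapping windows
    std::sort(cand.begin(), cand.end(), [](const Aln& a, const Aln& b) {
      if (a.cstart != b.cstart) return a.cstart < b.cstart;
      if (a.cend != b.cend) return a.cend < b.cend;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.score > b.score;
    });
    cand.erase(std::unique(cand.begin(), cand.end(),
                           [](const Aln& a, const Aln& b) {
                             return a.cstart == b.cstart && a.cend == b.cend &&
                                    a.strand == b.strand;
                           }),
               cand.end());
    // collapse overlapping hits of this read: keep best score per locus
    std::sort(cand.begin(), cand.end(), cand_lt);
    std::vector<Aln> kept;
    for (const Aln& a : cand) {
      bool clash = false;
      for (const Aln& k : kept)
        if (a.cstart < k.cend && k.cstart < a.cend) { clash = true; break; }
      if (!clash) kept.push_back(a);
    }
    for (const Aln& a : kept) { out_hits.push_back(a); out_ridx.push_back(r + 1); }
  }
  return hits_frame(out_hits, out_ridx);
}

// Full Smith-Waterman verification oracle: iteratively extracts the global
// best local alignment over both strands, blocks its contig footprint, and
// repeats until nothing at or above the cutoff remains.
// [[Rcpp::export]]
DataFrame sw_oracle_cpp(std::string read, std::string contig, int match,
                        int mismatch, int gap, double min_identity,
                        int min_score, int min_len) {
  bool score_mode = (min_score != NA_INTEGER);
  int floor_sc = score_floor(score_mode, min_score, min_identity, min_len);
  int clen = (int)contig.size();
  std::string rc = revcomp1(read);
  int m = (int)read.size();
  std::vector<char> blocked(clen, 0);
  std::vector<Aln> hits;
  std::vector<int> ridx;
  for (int iter = 0; iter < 4096; ++iter) {
    Aln ap, am;
    bool okp = sw_best(read, contig, 0, clen, match, mismatch, gap, &blocked, ap);
    bool okm = sw_best(rc, contig, 0, clen, match, mismatch, gap, &blocked, am);
    ap.strand = 0; am.strand = 1;
    if (okm) { int rs = m - am.rend, re = m - am.rstart; am.rstart = rs; am.rend = re; }
    Aln* pick = nullptr;
    if (okp && okm) pick = cand_lt(ap, am) ? &ap : &am;
    else if (okp) pick = &ap;
    else if (okm) pick = &am;
    if (!pick || pick->score < floor_sc) break;
    if (passes(*pick, score_mode, min_score, min_identity, min_len)) {
      hits.push_back(*pick);
      ridx.push_back(1);
    }
    for (int p = pick->cstart; p < pick->cend; ++p) blocked[p] = 1;
  }
  return hits_frame(hits, ridx);
}
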