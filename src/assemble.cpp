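// Core of the permissive consensus assembler: canonical k-mer seed
// selection, greedy bidirectional majority-rule extension, and fast
// ungapped read-vs-consensus matching used for read subtraction.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <deque>
#include <array>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

inline int bidx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}
const char BASES[4] = {'A', 'C', 'G', 'T'};

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

uint64_t rc_code(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (v & 3ULL)); v >>= 2; }
  return r;
}

std::string decode(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = BASES[v & 3ULL]; v >>= 2; }
  return s;
}

// Shannon entropy (bits) of base frequencies within a k-mer
double kmer_entropy(uint64_t v, int k) {
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < k; ++i) { cnt[v & 3ULL]++; v >>= 2; }
  double h = 0;
  for (int b = 0; b < 4; ++b) {
    if (cnt[b] == 0) continue;
    double p = (double)cnt[b] / k;
    h -= p * std::log2(p);
  }
  return h;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> ReadIndex;

ReadIndex build_read_index(const std::vector<std::string>& reads, int k) {
  ReadIndex idx;
  for (int r = 0; r < (int)reads.size(); ++r) {
    const std::string& s = reads[r];
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (encode(s.c_str() + p, k, v)) idx[v].push_back({r, p});
    }
  }
  return idx;
}

}  // namespace

// Most frequent canonical k-mer passing the low-complexity entropy filter.
// Ties broken by lexicographically smallest canonical k-mer.
// [[Rcpp::export]]
List select_seed_cpp(CharacterVector reads, int k, double min_entropy) {
  std::unordered_map<uint64_t, int> counts;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (!encode(s.c_str() + p, k, v)) continue;
      uint64_t canon = std::min(v, rc_code(v, k));
      counts[canon]++;
    }
  }
  uint64_t best = 0;
  int best_n = 0;
  bool found = false;
  for (auto& kv : counts) {
    if (kmer_entropy(kv.first, k) < min_entropy) continue;
    if (kv.second > best_n || (kv.second == best_n && (!found || kv.first < best))) {
      best = kv.first; best_n = kv.second; found = true;
    }
  }
  if (!found)
    return List::create(_["kmer"] = "", _["count"] = 0);
  return List::create(_["kmer"] = decode(best, k), _["count"] = best_n);
}

// Greedy bidirectional majority-rule extension of a seed k-mer.
// Reads are recruited when they overlap the current consensus by at least
// min_overlap columns at >= min_ov_ident identity (ungapped, both strands);
// new columns are fixed when their stacked depth reaches min_depth.
// [[Rcpp::export]]
List extend_consensus_cpp(CharacterVector reads_in, std::string seed,
                          int recruit_k, int min_overlap, double min_ov_ident,
                          int min_depth, int max_len,
                          NumericVector base_freq) {
  int n = reads_in.size();
  std::vector<std::string> reads(n), reads_rc(n);
  for (int i = 0; i < n; ++i) {
    reads[i] = as<std::string>(reads_in[i]);
    reads_rc[i] = revcomp1(reads[i]);
  }
  ReadIndex idx = build_read_index(reads, recruit_k);

  // consensus coordinates: seed occupies [0, slen); counts may extend wider
  int slen = (int)seed.size();
  int lo = 0, hi = slen;                 // consensus extent
  int clo = 0;                           // coordinate of counts.front()
  std::deque<std::array<int, 4>> counts(slen, std::array<int, 4>{0, 0, 0, 0});
  std::deque<char> cons(seed.begin(), seed.end());  // covers [lo, hi)

  auto grow_to = [&](int a, int b) {  // ensure counts cover [a, b)
    while (a < clo) { counts.push_front({0, 0, 0, 0}); --clo; }
    while (b > clo + (int)counts.size()) counts.push_back({0, 0, 0, 0});
  };
  auto depth_at = [&](int c) -> int {
    if (c < clo || c >= clo + (int)counts.size()) return 0;
    const auto& a = counts[c - clo];
    return a[0] + a[1] + a[2] + a[3];
  };
  auto majority_at = [&](int c) -> char {
    const auto& a = counts[c - clo];
    int best = -1;
    for (int b = 0; b < 4; ++b) {
      if (best < 0 || a[b] > a[best]) best = b;
      else if (a[b] == a[best]) {
        if (base_freq[b] > base_freq[best]) best = b;
        // equal frequency falls through to the lexicographically first base
      }
    }
    return BASES[best];
  };

  std::vector<char> recruited(n, 0);
  std::vector<int> rec_id, rec_off;
  std::vector<char> rec_strand;
  int support = 0;

  uint64_t seed_code;
  bool seed_ok = encode(seed.c_str(), std::min((int)seed.size(), recruit_k),
                        seed_code);
  (void)seed_ok;
  int tandem_period = 0;

  bool changed = true;
  while (changed && (hi - lo) < max_len && tandem_period == 0) {
    changed = false;
    // refresh majority characters: columns fixed provisionally at low
    // depth improve as later recruits stack onto them, which keeps
    // word-matching against the frontier effective
    for (int c = lo; c < hi; ++c)
      if (depth_at(c) > 0) cons[c - lo] = majority_at(c);
    // ---- recruit pass: candidates via shared words with the consensus
    std::map<int, std::vector<std::pair<int, int>>> cand;  // rid -> (strand, offset)
    std::string cstr(cons.begin(), cons.end());
    for (int c = 0; c + recruit_k <= (int)cstr.size(); ++c) {
      uint64_t v;
      if (!encode(cstr.c_str() + c, recruit_k, v)) continue;
      auto it = idx.find(v);
      if (it != idx.end())
        for (auto& pr : it->second)
          if (!recruited[pr.first])
            cand[pr.first].push_back({0, lo + c - pr.second});
      auto it2 = idx.find(rc_code(v, recruit_k));
      if (it2 != idx.end())
        for (auto& pr : it2->second)
          if (!recruited[pr.first]) {
            int L = (int)reads[pr.first].size();
            cand[pr.first].push_back({1, lo + c - (L - recruit_k - pr.second)});
          }
    }
    for (auto& kv : cand) {
      int rid = kv.first;
      auto& offs = kv.second;
      std::sort(offs.begin(), offs.end());
      offs.erase(std::unique(offs.begin(), offs.end()), offs.end());
      int L = (int)reads[rid].size();
      int best_match = -1, best_ov = 0, best_off = 0, best_st = 0;
      for (auto& so : offs) {
        int st = so.first, off = so.second;
        const std::string& q = st == 0 ? reads[rid] : reads_rc[rid];
        int a = std::max(off, lo), b = std::min(off + L, hi);
        int ov = b - a;
        // the seed may be shorter than min_overlap; never require more
        // overlap than the consensus currently offers
        if (ov < std::min(min_overlap, hi - lo)) continue;
        int mt = 0;
        for (int c = a; c < b; ++c)
          if (q[c - off] == cons[c - lo]) ++mt;
        if (mt > best_match ||
            (mt == best_match && (off < best_off || (off == best_off && st < best_st)))) {
          best_match = mt; best_ov = ov; best_off = off; best_st = st;
        }
      }
      if (best_match < 0) continue;
      if ((double)best_match / best_ov < min_ov_ident) continue;
      // recruit: stack the read's bases
      const std::string& q = best_st == 0 ? reads[rid] : reads_rc[rid];
      grow_to(best_off, best_off + L);
      for (int c = best_off; c < best_off + L; ++c) {
        int b = bidx(q[c - best_off]);
        if (b >= 0) counts[c - clo][b]++;
      }
      recruited[rid] = 1;
      rec_id.push_back(rid + 1);
      rec_off.push_back(best_off);
      rec_strand.push_back(best_st == 0 ? '+' : '-');
      ++support;
      changed = true;
    }
    // ---- extension pass
    // Extend provisionally at a low evidence threshold: reads recruited in
    // later passes stack onto these columns retroactively, so a column's
    // final depth is its full stack depth, not just the depth visible when
    // the boundary first reaches it.  Columns that never reach
    // min_column_depth are trimmed after convergence.
    int prov = 1;
    while (hi - lo < max_len && depth_at(hi) >= prov) {
      cons.push_back(majority_at(hi));
      ++hi;
      changed = true;
    }
    while (hi - lo < max_len && depth_at(lo - 1) >= prov) {
      cons.push_front(majority_at(lo - 1));
      --lo;
      changed = true;
    }
    // ---- tandem / circularity guard: seed word recurs out of phase
    if (changed && (int)cons.size() >= 2 * slen) {
      std::string cs(cons.begin(), cons.end());
      std::vector<int> occ;
      size_t p = cs.find(seed);
      while (p != std::string::npos) {
        occ.push_back((int)p);
        p = cs.find(seed, p + 1);
      }
      if (occ.size() >= 2) {
        int per = occ[1] - occ[0];
        for (size_t i = 2; i < occ.size(); ++i)
          per = std::min(per, occ[i] - occ[i - 1]);
        // terminal direct repeats of an LTR element also repeat the seed;
        // only short-period recurrence is a true tandem array
        if (per <= 200) tandem_period = per;
      }
    }
  }

  // trim terminal columns that never reached the depth requirement or
  // have no plurality base (overhang into unrelated flanking sequence)
  auto good_col = [&](int c) {
    int d = depth_at(c);
    if (d < min_depth) return false;
    const auto& a = counts[c - clo];
    int mx = std::max(std::max(a[0], a[1]), std::max(a[2], a[3]));
    return 2 * mx > d;  // strict plurality above 50%
  };
  while (hi - lo > slen && !good_col(hi - 1)) { cons.pop_back(); --hi; }
  while (hi - lo > slen && !good_col(lo)) { cons.pop_front(); ++lo; }

  // final consensus: most common base at each covered position
  for (int c = lo; c < hi; ++c)
    if (depth_at(c) > 0) cons[c - lo] = majority_at(c);

  std::string consensus(cons.begin(), cons.end());
  IntegerVector depth(hi - lo);
  for (int c = lo; c < hi; ++c) depth[c - lo] = depth_at(c);

  // tandem arrays shorter than two seed spans never trigger the in-loop
  // guard; detect residual periodicity by autocorrelation instead
  if (tandem_period == 0) {
    int len = (int)consensus.size();
    for (int p = 5; p <= 200 && len - p >= 12; ++p) {
      int mt = 0;
      for (int c = 0; c + p < len; ++c)
        if (consensus[c] == consensus[c + p]) ++mt;
      if ((double)mt / (len - p) >= 0.9) { tandem_period = p; break; }
    }
  }

  // tandem arrays: report one consensus unit at the deepest phase
  if (tandem_period > 0 && tandem_period < (hi - lo)) {
    int per = tandem_period;
    long best_sum = -1;
    int best_s = lo;
    for (int s = lo; s + per <= hi && s < lo + per; ++s) {
      long sm = 0;
      for (int c = s; c < s + per; ++c) sm += depth_at(c);
      if (sm > best_sum) { best_sum = sm; best_s = s; }
    }
    consensus = consensus.substr(best_s - lo, per);
    IntegerVector d2(per);
    for (int c = best_s; c < best_s + per; ++c) d2[c - best_s] = depth_at(c);
    depth = d2;
  }

  IntegerVector off_out(rec_off.size());
  for (size_t i = 0; i < rec_off.size(); ++i) off_out[i] = rec_off[i] - lo;
  CharacterVector st_out(rec_strand.size());
  for (size_t i = 0; i < rec_strand.size(); ++i)
    st_out[i] = std::string(1, rec_strand[i]);

  return List::create(
      _["consensus"] = consensus, _["depth"] = depth,
      _["support"] = support, _["read_id"] = wrap(rec_id),
      _["offset"] = off_out, _["strand"] = st_out,
      _["tandem_period"] = tandem_period);
}

// Best ungapped read-vs-consensus match per read (both strands), candidate
// offsets proposed by shared words. Used for read subtraction between
// assembly rounds.
// [[Rcpp::export]]
DataFrame match_reads_cpp(CharacterVector reads_in, std::string consensus,
                          int k, double min_identity, int min_overlap) {
  int n = reads_in.size();
  int clen = (int)consensus.size();
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for (int p = 0; p + k <= clen; ++p) {
    uint64_t v;
    if (encode(consensus.c_str() + p, k, v)) idx[v].push_back(p);
  }
  LogicalVector matched(n);
  NumericVector identity(n);
  IntegerVector overlap(n);
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads_in[r]);
    int L = (int)fwd.size();
    int best_m = -1, best_ov = 0;
    for (int st = 0; st < 2; ++st) {
      std::string q = st == 0 ? fwd : revcomp1(fwd);
      std::vector<int> offs;
      for (int i = 0; i + k <= L; ++i) {
        uint64_t v;
        if (!encode(q.c_str() + i, k, v)) continue;
        auto it = idx.find(v);
        if (it == idx.end()) continue;
        for (int cp : it->second) offs.push_back(cp - i);
      }
      std::sort(offs.begin(), offs.end());
      offs.erase(std::unique(offs.begin(), offs.end()), offs.end());
      for (int off : offs) {
        int a = std::max(off, 0), b = std::min(off + L, clen);
        int ov = b - a;
        if (ov < min_overlap) continue;
        int mt = 0;
        for (int c = a; c < b; ++c)
          if (q[c - off] == consensus[c]) ++mt;
        if (mt > best_m) { best_m = mt; best_ov = ov; }
      }
    }
    if (best_m >= 0) {
      identity[r] = (double)best_m / best_ov;
      overlap[r] = best_ov;
      matched[r] = identity[r] >= min_identity;
    } else {
      identity[r] = 0; overlap[r] = 0; matched[r] = false;
    }
  }
  return DataFrame::create(_["matched"] = matched, _["identity"] = identity,
                           _["overlap"] = overlap,
                           _["stringsAsFactors"] = false);
}
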