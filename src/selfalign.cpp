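// Word-seeded ungapped self-comparison of a contig with X-drop extension.
// Reports same-strand (direct) repeat alignments off the main diagonal;
// used for candidate-LTR pair discovery and terminal-repeat detection on
// assembled consensi.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
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

}  // namespace

// [[Rcpp::export]]
DataFrame self_align_cpp(std::string contig, int word_size, int min_len,
                         double min_identity, int xdrop, int max_occ) {
  int n = (int)contig.size();
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for (int p = 0; p + word_size <= n; ++p) {
    uint64_t v;
    if (encode(contig.c_str() + p, word_size, v)) idx[v].push_back(p);
  }
  // per-diagonal position already explained by an accepted/visited extension
  std::map<int, int> covered;
  std::vector<int> s1v, e1v, s2v, e2v, lenv, nmv;
  std::vector<double> idv;

  for (int i = 0; i + word_size <= n; ++i) {
    uint64_t v;
    if (!encode(contig.c_str() + i, word_size, v)) continue;
    auto it = idx.find(v);
    if (it == idx.end()) continue;
    const std::vector<int>& occ = it->second;
    if ((int)occ.size() > max_occ) continue;  // low-complexity / hyper-repeated word
    for (int j : occ) {
      if (j <= i) continue;  // one orientation of each pair; skip main diagonal
      int d = j - i;
      auto cv = covered.find(d);
      if (cv != covered.end() && i < cv->second) continue;
      // ungapped X-drop extension around the seed on diagonal d
      int score = word_size, best = score;
      int right = i + word_size;  // exclusive end on first interval
      int p = i + word_size;
      while (p + d < n) {
        score += (contig[p] == contig[p + d]) ? 1 : -1;
        ++p;
        if (score > best) { best = score; right = p; }
        if (best - score >= xdrop) break;
      }
      score = best;
      int left = i;
      p = i - 1;
      while (p >= 0) {
        score += (contig[p] == contig[p + d]) ? 1 : -1;
        --p;
        if (score > best) { best = score; left = p + 1; }
        if (best - score >= xdrop) break;
      }
      int len = right - left;
      covered[d] = right;
      if (len < min_len) continue;
      int nm = 0;
      for (int q = left; q < right; ++q)
        if (contig[q] == contig[q + d]) ++nm;
      double id = (double)nm / len;
      if (id < min_identity) continue;
      s1v.push_back(left); e1v.push_back(right);
      s2v.push_back(left + d); e2v.push_back(right + d);
      lenv.push_back(len); nmv.push_back(nm); idv.push_back(id);
    }
  }
  return DataFrame::create(
      _["start1"] = wrap(s1v), _["end1"] = wrap(e1v), _["start2"] = wrap(s2v),
      _["end2"] = wrap(e2v), _["length"] = wrap(lenv),
      _["n_match"] = wrap(nmv), _["identity"] = wrap(idv),
      _["stringsAsFactors"] = false);
}
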