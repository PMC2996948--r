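// Sequence primitives used by the simulator and the test helpers.
// All randomness draws from R's RNG so set.seed() controls everything.
#include <Rcpp.h>
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

// substitute each base with prob `rate`, always to a different base
int mutate_inplace(std::string& s, double rate) {
  int nsub = 0;
  if (rate <= 0) return 0;
  for (char& c : s) {
    int b = bidx(c);
    if (b < 0) continue;
    if (unif_rand() < rate) {
      int repl = (b + 1 + (int)(unif_rand() * 3.0)) % 4;
      if (repl == b) repl = (b + 1) % 4;  // fp guard
      c = BASES[repl];
      ++nsub;
    }
  }
  return nsub;
}

}  // namespace

// [[Rcpp::export]]
std::string random_dna_cpp(int n, NumericVector probs) {
  double c1 = probs[0], c2 = c1 + probs[1], c3 = c2 + probs[2];
  std::string s((size_t)n, 'A');
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    s[i] = u < c1 ? 'A' : (u < c2 ? 'C' : (u < c3 ? 'G' : 'T'));
  }
  return s;
}

// [[Rcpp::export]]
List mutate_seq_cpp(std::string s, double rate) {
  int nsub = mutate_inplace(s, rate);
  return List::create(_["seq"] = s, _["n_sub"] = nsub);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp1(as<std::string>(x[i]));
  return out;
}

// Extract fixed-length reads at 1-based `starts`; minus-strand reads are
// reverse-complemented; substitution errors applied at `error_rate`.
// [[Rcpp::export]]
List extract_reads_cpp(std::string genome, IntegerVector starts, int len,
                       LogicalVector minus, double error_rate) {
  int n = starts.size();
  CharacterVector reads(n);
  IntegerVector nerr(n);
  for (int i = 0; i < n; ++i) {
    std::string r = genome.substr(starts[i] - 1, len);
    if (minus[i]) r = revcomp1(r);
    nerr[i] = mutate_inplace(r, error_rate);
    reads[i] = r;
  }
  return List::create(_["reads"] = reads, _["n_errors"] = nerr);
}

// Per-pair mismatch counts between equal-length strings (test oracle helper).
// [[Rcpp::export]]
IntegerVector count_mismatches_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    int m = 0;
    size_t L = std::min(x.size(), y.size());
    for (size_t j = 0; j < L; ++j) if (x[j] != y[j]) ++m;
    out[i] = m;
  }
  return out;
}

// Max identity per position over a set of covering intervals
// (0-based half-open starts/ends on a vector of length len).
// [[Rcpp::export]]
NumericVector bin_cover_cpp(int len, IntegerVector starts, IntegerVector ends,
                            NumericVector identity) {
  NumericVector out(len, 0.0);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    int a = std::max(starts[i], 0), b = std::min(ends[i], len);
    double id = identity[i];
    for (int p = a; p < b; ++p) if (id > out[p]) out[p] = id;
  }
  return out;
}
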