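#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Lempel-Ziv (1976) production count, exhaustive-history parse with
// self-overlap allowed; the final, possibly non-exhaustive component counts
// once.  Calibration: 19 distinct symbols -> 19, a 19-symbol homopolymer -> 2.
static int lz76_one(const char *s, const int n) {
  if (n <= 0) return NA_INTEGER;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  for (;;) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// [[Rcpp::export(rng = false)]]
IntegerVector lz76_cpp(CharacterVector x) {
  const R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    if (CharacterVector::is_na(x[j])) { out[j] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(x, j));
    out[j] = lz76_one(s, (int) LENGTH(STRING_ELT(x, j)));
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
IntegerVector tile_lz76_cpp(std::string s, int window) {
  const int n = (int) s.size();
  const int m = n - window + 1;
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = lz76_one(s.c_str() + i, window);
  return out;
}

// Nussinov maximum base-pairing dynamic program over codes 0=A,1=U/T,2=G,3=C.
// Watson-Crick pairs plus the G.U wobble; hairpin loops of at least min_loop
// unpaired bases.
static inline bool can_pair(const int a, const int b, const bool wobble) {
  return (a == 0 && b == 1) || (a == 1 && b == 0) ||             // A:U
         (a == 2 && b == 3) || (a == 3 && b == 2) ||             // G:C
         (wobble && ((a == 2 && b == 1) || (a == 1 && b == 2))); // G:U
}

// [[Rcpp::export(rng = false)]]
int nussinov_cpp(IntegerVector code, int min_loop, bool wobble) {
  const int n = code.size();
  if (n < 2) return 0;
  std::vector<int> M((size_t) n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      int best = M[(size_t) (i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(code[i], code[k], wobble)) continue;
        int v = 1;
        if (k - i >= 2) v += M[(size_t) (i + 1) * n + (k - 1)];
        if (k + 1 <= j) v += M[(size_t) (k + 1) * n + j];
        if (v > best) best = v;
      }
      M[(size_t) i * n + j] = best;
    }
  }
  return M[(size_t) 0 * n + (n - 1)];
}
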