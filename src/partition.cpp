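#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(exp(a) + exp(b)) without overflow
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

// Nested-structure partition function over base-pair energies, log space.
// s: sequence encoded 0=A,1=C,2=G,3=U. logw: 4x4 matrix of log Boltzmann
// weights per pair type (-Inf = not pairable). forced: per-position partner
// index (0-based) or -1 if unconstrained; forced pairs must be mutually
// consistent and nested (validated in R). min_loop: minimum unpaired
// nucleotides enclosed by a pair (hairpin steric limit).
//
// Recursion on interval [i..j], conditioning on the fate of i:
//   Z(i,j) = [i unpaired] Z(i+1,j)
//          + sum_k w(i,k) * Z(i+1,k-1) * Z(k+1,j)
// Every nested structure is generated exactly once. The open chain has
// weight 1, so the unconstrained Z is always >= 1.
// [[Rcpp::export]]
double pf_log_z_cpp(IntegerVector s, NumericMatrix logw, IntegerVector forced,
                    int min_loop) {
  const int n = s.size();
  if (n == 0) return 0.0;
  std::vector<double> Z((size_t)n * n, 0.0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };
  auto getZ = [&](int i, int j) { return (i > j) ? 0.0 : Z[idx(i, j)]; };
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double acc = R_NegInf;
      if (forced[i] < 0) acc = getZ(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const double w = logw(s[i], s[k]);
        if (w == R_NegInf) continue;
        if (forced[i] >= 0 && forced[i] != k) continue;
        if (forced[k] >= 0 && forced[k] != i) continue;
        acc = logadd(acc, w + getZ(i + 1, k - 1) + getZ(k + 1, j));
      }
      Z[idx(i, j)] = acc;
    }
  }
  return getZ(0, n - 1);
}

// Exact base-pair probabilities p(i,j) by the inside-outside method on the
// same recursion. D(a,b) is the log outside weight of subproblem Z(a,b):
// the Boltzmann weight of all ways the rest of the sequence can fold given
// that [a..b] is an independent subproblem. p(a,k) then sums, over every
// subproblem in which the pair (a,k) can close, outside * w * inside-left *
// inside-right, normalized by the total partition function.
// [[Rcpp::export]]
NumericMatrix bp_prob_cpp(IntegerVector s, NumericMatrix logw, int min_loop) {
  const int n = s.size();
  NumericMatrix P(n, n);
  if (n == 0) return P;
  std::vector<double> Z((size_t)n * n, 0.0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };
  auto getZ = [&](int i, int j) { return (i > j) ? 0.0 : Z[idx(i, j)]; };
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double acc = getZ(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const double w = logw(s[i], s[k]);
        if (w == R_NegInf) continue;
        acc = logadd(acc, w + getZ(i + 1, k - 1) + getZ(k + 1, j));
      }
      Z[idx(i, j)] = acc;
    }
  }
  const double logZtot = getZ(0, n - 1);

  std::vector<double> D((size_t)n * n, R_NegInf);
  D[idx(0, n - 1)] = 0.0;
  for (int len = n; len >= 1; --len) {
    for (int a = 0; a + len - 1 < n; ++a) {
      const int b = a + len - 1;
      const double d = D[idx(a, b)];
      if (d == R_NegInf) continue;
      if (a + 1 <= b) D[idx(a + 1, b)] = logadd(D[idx(a + 1, b)], d);
      for (int k = a + min_loop + 1; k <= b; ++k) {
        const double w = logw(s[a], s[k]);
        if (w == R_NegInf) continue;
        if (a + 1 <= k - 1) {
          D[idx(a + 1, k - 1)] =
              logadd(D[idx(a + 1, k - 1)], d + w + getZ(k + 1, b));
        }
        if (k + 1 <= b) {
          D[idx(k + 1, b)] =
              logadd(D[idx(k + 1, b)], d + w + getZ(a + 1, k - 1));
        }
      }
    }
  }

  for (int a = 0; a < n; ++a) {
    for (int k = a + min_loop + 1; k < n; ++k) {
      const double w = logw(s[a], s[k]);
      if (w == R_NegInf) continue;
      double outer = R_NegInf;
      for (int b = k; b < n; ++b) {
        const double d = D[idx(a, b)];
        if (d == R_NegInf) continue;
        outer = logadd(outer, d + getZ(k + 1, b));
      }
      if (outer == R_NegInf) continue;
      P(a, k) = std::exp(w + getZ(a + 1, k - 1) + outer - logZtot);
    }
  }
  return P;
}
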