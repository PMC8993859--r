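#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Match-length profiles for Lempel-Ziv style entropy estimators.
//
// Convention (fixed across the package): Lambda_i = L_i + 1, where L_i is the
// length of the longest contiguous substring starting at position i of the
// target that also occurs contiguously inside the admissible reference prefix,
// with L_i capped at N - i + 1 (1-based). Lambda_1 = 1 in self mode.
//
// Fast paths index the growing reference prefix by single symbols (length-1
// matches) and by adjacent symbol pairs (seeds for longer matches), giving
// sub-quadratic expected time on non-degenerate sequences. Correctness is
// defined solely by agreement with the brute-force oracles below, which share
// no code with the fast paths.

typedef std::unordered_map<long long, std::vector<int> > PairIndex;

static inline long long pair_key(int s1, int s2, long long base) {
  return (long long)s1 * base + (long long)s2;
}

// [[Rcpp::export]]
IntegerVector self_lambda_fast(IntegerVector a) {
  const int n = a.size();
  IntegerVector lam(n);
  if (n == 0) return lam;
  long long base = 0;
  for (int i = 0; i < n; ++i) if (a[i] > base) base = a[i];
  base += 1;
  std::vector<char> seen((size_t)base, 0);
  PairIndex pairs;
  for (int i = 0; i < n; ++i) {
    // index lags behind: symbols up to i-1, pairs up to (i-2, i-1)
    if (i >= 1) seen[a[i - 1]] = 1;
    if (i >= 2) pairs[pair_key(a[i - 2], a[i - 1], base)].push_back(i - 2);
    const int cap = n - i; // max admissible L (1-based N - i + 1)
    int L = 0;
    if (seen[a[i]]) L = 1;
    if (L > 0 && cap >= 2 && i + 1 < n) {
      PairIndex::const_iterator it = pairs.find(pair_key(a[i], a[i + 1], base));
      if (it != pairs.end()) {
        const std::vector<int>& js = it->second;
        for (size_t u = 0; u < js.size(); ++u) {
          const int j = js[u];
          const int maxlen = std::min(cap, i - j); // match must end before i
          if (maxlen <= L) continue;
          int k = 2;
          while (k < maxlen && a[j + k] == a[i + k]) ++k;
          if (k > L) L = k;
          if (L == cap) break;
        }
      }
    }
    if (L > cap) L = cap;
    lam[i] = L + 1;
  }
  return lam;
}

// [[Rcpp::export]]
IntegerVector cross_lambda_fast(IntegerVector a, NumericVector ta,
                                IntegerVector b, NumericVector tb,
                                bool time_constrained) {
  const int na = a.size(), nb = b.size();
  IntegerVector lam(na);
  if (na == 0) return lam;
  long long base = 0;
  for (int i = 0; i < na; ++i) if (a[i] > base) base = a[i];
  for (int j = 0; j < nb; ++j) if (b[j] > base) base = b[j];
  base += 1;
  std::vector<char> seen((size_t)base, 0);
  PairIndex pairs;
  int m = 0; // number of B events admitted to the reference prefix
  if (!time_constrained) {
    for (int j = 0; j < nb; ++j) {
      seen[b[j]] = 1;
      if (j >= 1) pairs[pair_key(b[j - 1], b[j], base)].push_back(j - 1);
    }
    m = nb;
  }
  for (int i = 0; i < na; ++i) {
    if (time_constrained) {
      while (m < nb && tb[m] < ta[i]) { // strict: simultaneous events are not previous
        seen[b[m]] = 1;
        if (m >= 1) pairs[pair_key(b[m - 1], b[m], base)].push_back(m - 1);
        ++m;
      }
    }
    const int cap = na - i;
    int L = 0;
    if (seen[a[i]]) L = 1;
    if (L > 0 && cap >= 2 && i + 1 < na) {
      PairIndex::const_iterator it = pairs.find(pair_key(a[i], a[i + 1], base));
      if (it != pairs.end()) {
        const std::vector<int>& js = it->second;
        for (size_t u = 0; u < js.size(); ++u) {
          const int j = js[u];
          if (j + 1 >= m) continue; // pair must lie wholly inside the prefix
          const int maxlen = std::min(cap, m - j);
          if (maxlen <= L) continue;
          int k = 2;
          while (k < maxlen && b[j + k] == a[i + k]) ++k;
          if (k > L) L = k;
          if (L == cap) break;
        }
      }
    }
    if (L > cap) L = cap;
    lam[i] = L + 1;
  }
  return lam;
}

// ---- brute-force oracles: direct translation of the definitions ----

// [[Rcpp::export]]
IntegerVector self_lambda_oracle(IntegerVector a) {
  const int n = a.size();
  IntegerVector lam(n);
  for (int i = 0; i < n; ++i) {
    const int cap = n - i;
    int L = 0;
    for (int len = 1; len <= cap; ++len) {
      bool found = false;
      for (int j = 0; j + len <= i && !found; ++j) {
        bool eq = true;
        for (int k = 0; k < len; ++k)
          if (a[j + k] != a[i + k]) { eq = false; break; }
        found = eq;
      }
      if (found) L = len; else break;
    }
    lam[i] = L + 1;
  }
  return lam;
}

// [[Rcpp::export]]
IntegerVector cross_lambda_oracle(IntegerVector a, NumericVector ta,
                                  IntegerVector b, NumericVector tb,
                                  bool time_constrained) {
  const int na = a.size(), nb = b.size();
  IntegerVector lam(na);
  for (int i = 0; i < na; ++i) {
    int m = nb;
    if (time_constrained) {
      m = 0;
      while (m < nb && tb[m] < ta[i]) ++m;
    }
    const int cap = na - i;
    int L = 0;
    for (int len = 1; len <= cap; ++len) {
      bool found = false;
      for (int j = 0; j + len <= m && !found; ++j) {
        bool eq = true;
        for (int k = 0; k < len; ++k)
          if (b[j + k] != a[i + k]) { eq = false; break; }
        found = eq;
      }
      if (found) L = len; else break;
    }
    lam[i] = L + 1;
  }
  return lam;
}
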