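#include <Rcpp.h>
using namespace Rcpp;

// Longest common contiguous substring length between two code-point vectors,
// O(|a| * |b|) time with a rolling row.
static int lcs_len(const IntegerVector& a, const IntegerVector& b) {
  const int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return 0;
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  int best = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector a, IntegerVector b) {
  return lcs_len(a, b);
}

// Mean over all unordered pairs of 1 - lcs(a, b) / max(|a|, |b|).
// texts is a list of integer vectors of Unicode code points.
// [[Rcpp::export]]
double mean_pairwise_dissimilarity_cpp(List texts) {
  const int n = texts.size();
  if (n < 2) return NA_REAL;
  double total = 0.0;
  long npairs = 0;
  std::vector<IntegerVector> tv(n);
  for (int i = 0; i < n; ++i) tv[i] = texts[i];
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int la = tv[i].size(), lb = tv[j].size();
      const int mx = la > lb ? la : lb;
      double d = (mx == 0) ? 0.0 : 1.0 - (double)lcs_len(tv[i], tv[j]) / mx;
      total += d;
      ++npairs;
    }
  }
  return total / npairs;
}
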