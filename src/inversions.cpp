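#include <Rcpp.h>
#include <vector>

// Inversion counting by bottom-up merge sort. An inversion is a pair of
// positions i < j with z[i] > z[j]; nothing is counted when z[i] <= z[j].
// The count can exceed 2^31 for long inputs (max n(n-1)/2), so tallies are
// kept in long long and returned as doubles.

// [[Rcpp::export]]
Rcpp::NumericVector count_inversions_cpp(Rcpp::NumericVector z) {
  const R_xlen_t n = z.size();
  long long inv = 0, comp = 0;
  std::vector<double> a(z.begin(), z.end());
  std::vector<double> buf(n);
  for (R_xlen_t width = 1; width < n; width *= 2) {
    for (R_xlen_t l = 0; l < n - width; l += 2 * width) {
      const R_xlen_t m = l + width - 1;
      const R_xlen_t r = std::min(l + 2 * width - 1, n - 1);
      R_xlen_t i = l, j = m + 1, k = l;
      while (i <= m && j <= r) {
        ++comp;
        if (a[i] <= a[j]) {
          buf[k++] = a[i++];
        } else {
          // everything still unmerged in the left half outranks a[j]
          inv += (long long)(m - i + 1);
          buf[k++] = a[j++];
        }
      }
      while (i <= m) buf[k++] = a[i++];
      while (j <= r) buf[k++] = a[j++];
      for (R_xlen_t t = l; t <= r; ++t) a[t] = buf[t];
    }
  }
  return Rcpp::NumericVector::create(
    Rcpp::Named("inversions") = (double)inv,
    Rcpp::Named("comparisons") = (double)comp);
}
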