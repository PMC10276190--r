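#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Bootstrap SD of the sample median: n_iter with-replacement resamples,
// median via nth_element. Uses R's RNG so results are reproducible with
// set.seed() on the R side.
// [[Rcpp::export]]
double boot_median_sd(NumericVector x, int n_iter) {
  int n = x.size();
  std::vector<double> buf(n);
  std::vector<double> med(n_iter);
  for (int b = 0; b < n_iter; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j == n) j = n - 1;
      buf[i] = x[j];
    }
    int k = n / 2;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double m = buf[k];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + k);
      m = (m + lo) / 2.0;
    }
    med[b] = m;
  }
  double s = 0.0, s2 = 0.0;
  for (int b = 0; b < n_iter; ++b) s += med[b];
  double mean = s / n_iter;
  for (int b = 0; b < n_iter; ++b) s2 += (med[b] - mean) * (med[b] - mean);
  return std::sqrt(s2 / (n_iter - 1));
}
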