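#include <Rcpp.h>
using namespace Rcpp;

// Luria-Delbruck probability mass function by the Ma-Sandri-Sarkar recursion:
//   p_0 = exp(-m),  p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1)
// [[Rcpp::export(name = ".ld_pmf_cpp")]]
NumericVector ld_pmf_cpp(double m, int k_max) {
  if (m <= 0.0) stop("parameter error: m must be positive");
  if (k_max < 0) stop("parameter error: k_max must be non-negative");
  NumericVector p(k_max + 1);
  p[0] = std::exp(-m);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    for (int i = 0; i < k; ++i) acc += p[i] / (double)(k - i + 1);
    p[k] = (m / (double)k) * acc;
  }
  return p;
}
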