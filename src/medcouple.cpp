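#include <Rcpp.h>
using namespace Rcpp;

// Naive O(n_left * n_right) medcouple on pre-sorted data. Callers thin
// large samples to evenly spaced order statistics first (see R wrapper),
// which keeps the kernel evaluation count bounded.
// Kernel: h(xi, xj) = ((xj - m) - (m - xi)) / (xj - xi) over xi <= m <= xj;
// pairs with xi == xj (only possible at the median) contribute 0, an
// adequate convention for continuous analyte data.
// [[Rcpp::export(name = ".medcouple_sorted")]]
double medcouple_sorted(NumericVector xs, double med) {
  const int n = xs.size();
  std::vector<double> h;
  h.reserve(1024);
  for (int i = 0; i < n && xs[i] <= med; ++i) {
    for (int j = n - 1; j >= 0 && xs[j] >= med; --j) {
      double xi = xs[i], xj = xs[j];
      if (xj > xi)
        h.push_back(((xj - med) - (med - xi)) / (xj - xi));
      else
        h.push_back(0.0);
    }
  }
  if (h.empty()) return 0.0;
  size_t m = h.size() / 2;
  std::nth_element(h.begin(), h.begin() + m, h.end());
  double hi = h[m];
  if (h.size() % 2 == 1) return hi;
  std::nth_element(h.begin(), h.begin() + m - 1, h.begin() + m);
  return 0.5 * (hi + h[m - 1]);
}
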