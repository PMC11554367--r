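#include <Rcpp.h>
using namespace Rcpp;

// r = p(n+1) percentile (CLSI nonparametric rank, = quantile type 6)
// of an unsorted buffer, by partial sort. Rank clamped to [1, n].
static double rank_quantile(std::vector<double>& v, double p) {
  const int n = v.size();
  double r = p * (n + 1.0);
  if (r < 1.0) r = 1.0;
  if (r > n) r = n;
  int lo = static_cast<int>(std::floor(r));
  double frac = r - lo;
  std::nth_element(v.begin(), v.begin() + (lo - 1), v.end());
  double xlo = v[lo - 1];
  if (frac <= 0.0 || lo >= n) return xlo;
  double xhi = *std::min_element(v.begin() + lo, v.end());
  return xlo + frac * (xhi - xlo);
}

// Percentile bootstrap of plain rank quantiles at each prob in `probs`.
// `idx` holds n_boot * n 1-based resample indices drawn in R so that all
// randomness flows through R's RNG (seed contract).
// Returns an n_boot x length(probs) matrix of resampled estimates.
// [[Rcpp::export(name = ".boot_rank_quantiles")]]
NumericMatrix boot_rank_quantiles(NumericVector x, IntegerVector idx, int n_boot,
                                  NumericVector probs) {
  const int n = x.size(), np = probs.size();
  NumericMatrix out(n_boot, np);
  std::vector<double> v(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) v[i] = x[idx[static_cast<size_t>(b) * n + i] - 1];
    for (int q = 0; q < np; ++q) {
      std::vector<double> tmp(v);
      out(b, q) = rank_quantile(tmp, probs[q]);
    }
  }
  return out;
}

// Weighted r = p(W+1) percentile of (value, weight) pairs; reduces to the
// plain rank quantile when every weight is 1.
static double weighted_rank_quantile(std::vector<std::pair<double, double> >& vw,
                                     double p) {
  std::sort(vw.begin(), vw.end());
  const int n = vw.size();
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += vw[i].second;
  double r = p * (W + 1.0);
  double cw = vw[0].second;
  if (r <= cw) return vw[0].first;
  for (int i = 1; i < n; ++i) {
    double cw2 = cw + vw[i].second;
    if (r <= cw2) {
      double span = cw2 - cw;
      double frac = span > 0.0 ? (r - cw) / span : 0.0;
      return vw[i - 1].first + frac * (vw[i].first - vw[i - 1].first);
    }
    cw = cw2;
  }
  return vw[n - 1].first;
}

// [[Rcpp::export(name = ".weighted_rank_quantile")]]
NumericVector weighted_rank_quantile_r(NumericVector x, NumericVector w,
                                       NumericVector probs) {
  const int n = x.size();
  NumericVector out(probs.size());
  for (int q = 0; q < probs.size(); ++q) {
    std::vector<std::pair<double, double> > vw(n);
    for (int i = 0; i < n; ++i) vw[i] = std::make_pair(x[i], w[i]);
    out[q] = weighted_rank_quantile(vw, probs[q]);
  }
  return out;
}

// Bootstrap of weighted rank quantiles: resample (value, weight) pairs.
// [[Rcpp::export(name = ".boot_weighted_quantiles")]]
NumericMatrix boot_weighted_quantiles(NumericVector x, NumericVector w,
                                      IntegerVector idx, int n_boot,
                                      NumericVector probs) {
  const int n = x.size(), np = probs.size();
  NumericMatrix out(n_boot, np);
  for (int b = 0; b < n_boot; ++b) {
    std::vector<std::pair<double, double> > vw(n);
    for (int i = 0; i < n; ++i) {
      int j = idx[static_cast<size_t>(b) * n + i] - 1;
      vw[i] = std::make_pair(x[j], w[j]);
    }
    std::sort(vw.begin(), vw.end());
    // quantiles share the sort: evaluate all probs on the sorted copy
    double W = 0.0;
    for (int i = 0; i < n; ++i) W += vw[i].second;
    for (int q = 0; q < np; ++q) {
      double r = probs[q] * (W + 1.0);
      double cw = vw[0].second;
      double val;
      if (r <= cw) {
        val = vw[0].first;
      } else {
        val = vw[n - 1].first;
        for (int i = 1; i < n; ++i) {
          double cw2 = cw + vw[i].second;
          if (r <= cw2) {
            double span = cw2 - cw;
            double frac = span > 0.0 ? (r - cw) / span : 0.0;
            val = vw[i - 1].first + frac * (vw[i].first - vw[i - 1].first);
            break;
          }
          cw = cw2;
        }
      }
      out(b, q) = val;
    }
  }
  return out;
}
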