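#include <Rcpp.h>
using namespace Rcpp;

// One EM run for a univariate Gaussian mixture from a given start.
// Log-likelihood is monotone non-decreasing by construction of the
// E/M updates; `check_monotone` aborts if floating-point noise ever
// violates that by more than 1e-8 * |ll| (debug aid).
// [[Rcpp::export(name = ".em_gauss")]]
List em_gauss(NumericVector x, NumericVector w0, NumericVector mu0,
              NumericVector sg0, double tol, int maxit, bool check_monotone) {
  const int n = x.size(), k = w0.size();
  std::vector<double> w(w0.begin(), w0.end()), mu(mu0.begin(), mu0.end()),
      sg(sg0.begin(), sg0.end()), g(static_cast<size_t>(n) * k);
  const double log2pi_half = 0.9189385332046727;  // log(sqrt(2*pi))
  double ll = R_NegInf, ll_old = R_NegInf;
  bool conv = false;
  int it;
  for (it = 1; it <= maxit; ++it) {
    // E-step + log-likelihood
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) / sg[j];
        double d = w[j] * std::exp(-0.5 * z * z - std::log(sg[j]) - log2pi_half);
        g[static_cast<size_t>(i) * k + j] = d;
        s += d;
      }
      if (s < 1e-300) s = 1e-300;
      ll += std::log(s);
      for (int j = 0; j < k; ++j) g[static_cast<size_t>(i) * k + j] /= s;
    }
    if (check_monotone && R_finite(ll_old) && ll < ll_old - 1e-8 * std::fabs(ll_old))
      stop("EM log-likelihood decreased (%.12g -> %.12g)", ll_old, ll);
    if (R_finite(ll_old) && std::fabs(ll - ll_old) <= tol * std::fabs(ll_old)) {
      conv = true;
      break;
    }
    ll_old = ll;
    // M-step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        double gij = g[static_cast<size_t>(i) * k + j];
        nk += gij;
        sx += gij * x[i];
      }
      if (nk < 1e-12) nk = 1e-12;
      double m = sx / nk, sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m;
        sv += g[static_cast<size_t>(i) * k + j] * d * d;
      }
      w[j] = nk / n;
      mu[j] = m;
      sg[j] = std::sqrt(std::max(sv / nk, 1e-12));
    }
  }
  return List::create(
      _["w"] = NumericVector(w.begin(), w.end()),
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["sg"] = NumericVector(sg.begin(), sg.end()), _["loglik"] = ll,
      _["converged"] = conv, _["n_iter"] = std::min(it, maxit));
}
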