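#include <Rcpp.h>
using namespace Rcpp;

// numerically safe log(1 + exp(x))
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log kernel of the integrand at random-effect value t for one observation:
//   m * (eta + t) - n * log(1 + exp(eta + t)) - t^2 / (2 v)
// (binomial normalizing constant and Gaussian constant added by the caller)
static inline double log_kernel(double m, double n, double eta, double t, double v) {
  double u = eta + t;
  return m * u - n * softplus(u) - t * t / (2.0 * v);
}

//' Per-observation marginal log-likelihood of the folded-binomial logistic
//' random-effect model, integrating the Gaussian random effect by adaptive
//' Gauss-Hermite quadrature centered at each observation's conditional mode.
//'
//' m: folded counts min(y, n - y); n: total counts; eta: linear predictor;
//' v: random-effect variance (v < 1e-12 collapses to the fixed-effect
//' binomial log-likelihood); gh_x / gh_logw: Gauss-Hermite nodes and log
//' weights for weight function exp(-x^2).
// [[Rcpp::export]]
NumericVector ase_obs_loglik_cpp(NumericVector m, NumericVector n,
                                 NumericVector eta, double v,
                                 NumericVector gh_x, NumericVector gh_logw) {
  int N = m.size(), K = gh_x.size();
  NumericVector out(N);
  bool novar = (v < 1e-12);
  std::vector<double> terms(K);
  for (int i = 0; i < N; ++i) {
    double mi = m[i], ni = n[i], et = eta[i];
    double lc = R::lchoose(ni, mi);
    if (novar) {
      out[i] = lc + mi * et - ni * softplus(et);
      continue;
    }
    // Newton iteration for the mode of the integrand; strictly concave in t
    double t = 0.0;
    for (int it = 0; it < 200; ++it) {
      double u = et + t;
      double s = 1.0 / (1.0 + std::exp(-u));
      double g = mi - ni * s - t / v;
      double h = -ni * s * (1.0 - s) - 1.0 / v;
      double step = g / h;
      t -= step;
      if (std::fabs(step) < 1e-11) break;
    }
    double u = et + t;
    double s = 1.0 / (1.0 + std::exp(-u));
    double curv = ni * s * (1.0 - s) + 1.0 / v; // -f''(mode)
    double sd = 1.0 / std::sqrt(curv);
    // adaptive rule: integral = sqrt(2) sd * sum_k w_k exp(x_k^2) g(t + sqrt(2) sd x_k)
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double tk = t + M_SQRT2 * sd * gh_x[k];
      double lt = gh_logw[k] + gh_x[k] * gh_x[k] + log_kernel(mi, ni, et, tk, v);
      terms[k] = lt;
      if (lt > mx) mx = lt;
    }
    double sm = 0.0;
    for (int k = 0; k < K; ++k) sm += std::exp(terms[k] - mx);
    out[i] = lc + std::log(M_SQRT2 * sd) + mx + std::log(sm)
      - 0.5 * std::log(2.0 * M_PI * v);
  }
  return out;
}
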