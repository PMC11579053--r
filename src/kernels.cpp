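#include <Rcpp.h>
using namespace Rcpp;

// Scalar Kalman filter with random-walk state dynamics, process variance
// q = 1 and measurement variance r = rho.  Per bin: prior mean = previous
// posterior mean, prior variance M = P + 1, gain K = M / (M + rho).
// [[Rcpp::export]]
List kalman_core(NumericVector y, double rho, double init_mean,
                 double init_var) {
  int n = y.size();
  NumericVector c_hat(n), kgain(n);
  double mean = init_mean, P = init_var;
  for (int t = 0; t < n; ++t) {
    double M = P + 1.0;
    double K = M / (M + rho);
    mean += K * (y[t] - mean);
    P = (1.0 - K) * M;
    c_hat[t] = mean;
    kgain[t] = K;
  }
  return List::create(_["c_hat"] = c_hat, _["kgain"] = kgain);
}

// Respiratory-state recursion: the prediction from the previous breath
// (alpha * x_{t-1} + (1 - alpha) * a_t) is combined with the sensory term
// (c_hat_t - c_ref) with update weight w_c.
// [[Rcpp::export]]
NumericVector state_core(NumericVector c_hat, NumericVector a, double alpha,
                         double w_c, double c_ref, double x0) {
  int n = c_hat.size();
  NumericVector x(n);
  double xp = x0;
  for (int t = 0; t < n; ++t) {
    xp = (1.0 - w_c) * (alpha * xp + (1.0 - alpha) * a[t])
         + w_c * (c_hat[t] - c_ref);
    x[t] = xp;
  }
  return x;
}
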