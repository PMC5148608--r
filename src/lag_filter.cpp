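#include <Rcpp.h>
using namespace Rcpp;

// First-order lag Tp*y' + y = u discretised with a causal zero-order hold:
// the sample u[n-1] is held over the interval (t[n-1], t[n]], giving the
// exact recursion y[n] = a*y[n-1] + (1-a)*u[n-1], a = exp(-dt/Tp), y[1] = 0
// (the decode window opens at rest). Columns are independent trials.
// [[Rcpp::export]]
NumericMatrix zoh_lag_filter(const NumericMatrix& u, double dt, double Tp) {
  const int n = u.nrow(), m = u.ncol();
  const double a = std::exp(-dt / Tp), b = 1.0 - a;
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    double yp = 0.0;
    for (int i = 1; i < n; ++i) {
      yp = a * yp + b * u(i - 1, j);
      y(i, j) = yp;
    }
  }
  return y;
}
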