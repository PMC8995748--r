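#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
//   min_a  0.5 a'Qa - sum(a)   s.t.  0 <= a_i <= C,  y'a = 0
// with Q_ij = y_i y_j K_ij. Maximal-violating-pair working-set
// selection; terminates when the KKT gap m(a) - M(a) <= tol.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double cost,
               double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // gradient of dual
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // m = max over I_up of -y G; M = min over I_low of -y G
    int i = -1, j = -1;
    double m = -std::numeric_limits<double>::infinity();
    double M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < cost) ||
                (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) ||
                 (y[t] < 0 && alpha[t] < cost);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M <= tol) break;

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double d = (m - M) / quad; // step along (y_i, -y_j) direction

    // box-clip the step so both alphas stay in [0, C]
    double lo, hi;
    if (y[i] > 0) { lo = -alpha[i]; hi = cost - alpha[i]; }
    else          { lo = alpha[i] - cost; hi = alpha[i]; }
    double lo2, hi2;
    if (y[j] > 0) { lo2 = alpha[j] - cost; hi2 = alpha[j]; }
    else          { lo2 = -alpha[j]; hi2 = cost - alpha[j]; }
    lo = std::max(lo, lo2); hi = std::min(hi, hi2);
    if (d > hi) d = hi;
    if (d < lo) d = lo;
    if (d == 0.0) break;

    double dai = y[i] * d, daj = -y[j] * d;
    alpha[i] += dai; alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // objective 0.5 a'Qa - sum a = 0.5 sum a_i (G_i - 1)  (since G = Qa - 1)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * alpha[t] * (G[t] - 1.0);

  // intercept: free SVs satisfy y_i f(x_i) = 1 => b = -y_i G_i
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-10 && alpha[t] < cost - 1e-10) {
      bsum += -y[t] * G[t]; ++nfree;
    }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else {
    double m = -std::numeric_limits<double>::infinity();
    double M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < cost) ||
                (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) ||
                 (y[t] < 0 && alpha[t] < cost);
      if (up && v > m) m = v;
      if (low && v < M) M = v;
    }
    b = (m + M) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = iter);
}
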