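#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for
//   min_{w,b}  0.5 * ||w||_1 + C * sum_i v_i * (y_i - b - x_i'w)^2
// with an unpenalized intercept (optional). Soft-thresholding updates; the
// residual vector is maintained incrementally.
// [[Rcpp::export(name = ".l1cd_cpp")]]
List l1cd_cpp(NumericMatrix X, NumericVector y, NumericVector v, double C,
              NumericVector w0, double b0, bool intercept,
              int max_iter, double tol) {
  int n = X.nrow(), p = X.ncol();
  NumericVector w = clone(w0);
  double b = intercept ? b0 : 0.0;

  std::vector<double> A(p);
  double vsum = 0.0;
  for (int i = 0; i < n; ++i) vsum += v[i];
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i] * X(i, j) * X(i, j);
    A[j] = 2.0 * C * s;
  }

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double f = b;
    for (int j = 0; j < p; ++j) f += X(i, j) * w[j];
    r[i] = y[i] - f;
  }

  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    if (intercept && vsum > 0) {
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += v[i] * r[i];
      double db = num / vsum;
      b += db;
      for (int i = 0; i < n; ++i) r[i] -= db;
      delta = std::abs(db);
    }
    for (int j = 0; j < p; ++j) {
      if (A[j] < 1e-14) continue;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += v[i] * X(i, j) * r[i];
      double z = 2.0 * C * g + A[j] * w[j];
      double wj = 0.0;
      if (z > 0.5) wj = (z - 0.5) / A[j];
      else if (z < -0.5) wj = (z + 0.5) / A[j];
      double dw = wj - w[j];
      if (dw != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= dw * X(i, j);
        if (std::abs(dw) > delta) delta = std::abs(dw);
        w[j] = wj;
      }
    }
    if (delta < tol) break;
  }
  return List::create(_["w"] = w, _["b"] = b);
}
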