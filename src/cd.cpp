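#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate-descent sweeps for the penalized weighted
// least-squares subproblem
//   min_b 0.5 * sum_i w_i (z_i - x_i'b)^2 + lalpha * ||b||_1 + 0.5 b'(twoQ)b
// given the current working residual r_i = w_i * (z_i - x_i'b). Each
// coordinate update is a closed-form soft-threshold; sweeps stop when the
// largest coordinate change falls below tol.
// [[Rcpp::export]]
List cd_sweeps(NumericMatrix xs, NumericVector w, NumericVector r,
               NumericVector beta, NumericMatrix twoQ, NumericVector wxx,
               double lalpha, double tol, int max_sweeps) {
  int n = xs.nrow(), p = xs.ncol();
  NumericVector b = clone(beta), rr = clone(r);
  int sweeps = 0;
  for (int s = 0; s < max_sweeps; ++s) {
    ++sweeps;
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) {
      double qb = 0.0;
      for (int k = 0; k < p; ++k) qb += twoQ(k, j) * b[k];
      qb -= twoQ(j, j) * b[j];
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += xs(i, j) * rr[i];
      num += wxx[j] * b[j] - qb;
      double denom = wxx[j] + twoQ(j, j);
      double bj = 0.0;
      if (denom > 0.0) {
        double a = std::fabs(num) - lalpha;
        if (a > 0.0) bj = (num > 0.0 ? a : -a) / denom;
      }
      double dj = bj - b[j];
      if (dj != 0.0) {
        for (int i = 0; i < n; ++i) rr[i] -= w[i] * xs(i, j) * dj;
        b[j] = bj;
        double adj = std::fabs(dj);
        if (adj > dmax) dmax = adj;
      }
    }
    if (dmax < tol) break;
  }
  return List::create(_["beta"] = b, _["r"] = rr, _["sweeps"] = sweeps);
}
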