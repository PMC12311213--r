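#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin C-SVC dual on a
// precomputed kernel matrix:
//
//   min_a  1/2 a^T Q a - e^T a   s.t.  0 <= a_i <= C,  y^T a = 0,
//
// with Q_ij = y_i y_j K_ij and G = Q a - e the dual gradient. Working
// pairs are the maximal violating pair with a second-order gain criterion
// for the partner; the feasible direction is u_i = y_i, u_j = -y_j (which
// preserves y^T a), the unconstrained step along it is violation /
// (K_ii + K_jj - 2 K_ij), and the step is clamped to the box. The
// decision value for a point x is sum_i a_i y_i K(x_i, x) + b.
//
// Used by the recursive-feature-elimination path, where the linear Gram
// matrix is downdated as features are dropped and refitting with a
// kernel-recomputing solver at every step would dominate the run time.
// Validated against libsvm (via e1071) in the test suite.

// [[Rcpp::export]]
List smo_svc(NumericMatrix K, IntegerVector y, double C, double eps = 1e-3,
             int max_iter = 4000000,
             Nullable<NumericVector> warm_start = R_NilValue) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  const double tau = 1e-12;
  const double *Kp = REAL(K);
  int iter = 0;

  // warm start from a feasible alpha (e.g. the previous elimination step):
  // rebuild the gradient G = Q alpha - e from the nonzero coordinates
  if (warm_start.isNotNull()) {
    NumericVector a0(warm_start);
    if (a0.size() == n) {
      for (int s = 0; s < n; ++s) {
        double as = std::min(std::max(a0[s], 0.0), C);
        alpha[s] = as;
        if (as != 0.0) {
          const double *Ks = Kp + (size_t)s * n;
          double cs = as * y[s];
          for (int t = 0; t < n; ++t) grad[t] += y[t] * cs * Ks[t];
        }
      }
    }
  }

  for (iter = 0; iter < max_iter; ++iter) {
    // i: argmax over I_up of -y_t G_t; also track min over I_low
    int i = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      if ((y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0))
        if (v > gmax) { gmax = v; i = t; }
      if ((y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C))
        if (v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < eps) break;
    const double *Ki = Kp + (size_t)i * n;
    const double Kii = Ki[i];

    // j: in I_low with positive violation, maximal second-order gain
    int j = -1;
    double best_gain = -1.0;
    for (int t = 0; t < n; ++t) {
      if ((y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C)) {
        double diff = gmax + y[t] * grad[t]; // gmax - (-y_t G_t)
        if (diff > 0) {
          double quad = Kii + Kp[(size_t)t * n + t] - 2.0 * Ki[t];
          if (quad <= 0) quad = tau;
          double gain = diff * diff / quad;
          if (gain > best_gain) { best_gain = gain; j = t; }
        }
      }
    }
    if (j < 0) break;
    const double *Kj = Kp + (size_t)j * n;

    // unconstrained step along (u_i, u_j) = (y_i, -y_j), clamped to the box
    double quad = Kii + Kj[j] - 2.0 * Ki[j];
    if (quad <= 0) quad = tau;
    double d = (gmax + y[j] * grad[j]) / quad;
    double hi = std::numeric_limits<double>::infinity();
    hi = std::min(hi, y[i] == 1 ? C - alpha[i] : alpha[i]);
    hi = std::min(hi, y[j] == 1 ? alpha[j] : C - alpha[j]);
    if (d > hi) d = hi;
    if (d <= 0) break;
    double dai = y[i] * d, daj = -y[j] * d;
    alpha[i] += dai;
    alpha[j] += daj;
    double ci = y[i] * dai, cj = y[j] * daj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (ci * Ki[t] + cj * Kj[t]);
  }

  // bias: average of -y_t G_t over free support vectors; otherwise the
  // midpoint of the KKT interval from the bounded points
  double bsum = 0.0; int nfree = 0;
  double ub = std::numeric_limits<double>::infinity(), lb = -ub;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * grad[t];
    if (alpha[t] > 0 && alpha[t] < C) { bsum += v; ++nfree; }
    else if ((y[t] == 1 && alpha[t] == 0) || (y[t] == -1 && alpha[t] == C))
      lb = std::max(lb, v);
    else
      ub = std::min(ub, v);
  }
  double b = nfree > 0 ? bsum / nfree : (ub + lb) / 2.0;

  NumericVector coef(n);
  for (int t = 0; t < n; ++t) coef[t] = alpha[t] * y[t];
  return List::create(_["coef"] = coef, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
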