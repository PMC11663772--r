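#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear C-SVC trained by SMO with maximal-violating-pair working-set
// selection. Solves
//   min 1/2 a' Q a - e' a   s.t. y' a = 0, 0 <= a <= C,  Q_ij = y_i y_j x_i'x_j
// and returns the primal hyperplane (w, b) with decision f(x) = w'x + b,
// oriented so y = +1 is the positive side. Written for the small dense
// problems of leave-one-out folds (n <= a few hundred), where a compiled
// solver removes per-fit call overhead from the nested-CV hot path.

// [[Rcpp::export]]
List smo_linear_cpp(const NumericMatrix& X, const NumericVector& y,
                    double C, double eps, int max_iter) {
  const int n = X.nrow(), d = X.ncol();
  const double TAU = 1e-12;

  // dense Gram matrix
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X(i, k) * X(j, k);
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Q a - e
  int iter = 0;
  bool converged = false;
  double Gmax = 0.0, Gmin = 0.0;

  while (iter < max_iter) {
    // working-set selection: i = argmax_{I_up} -y G, j = argmin_{I_low} -y G
    Gmax = -HUGE_VAL; Gmin = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up  && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) { converged = true; break; }

    const double ai_old = alpha[i], aj_old = alpha[j];
    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj - 2.0 * Kij; // Qii + Qjj + 2Qij with yi*yj = -1
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) { converged = true; break; }
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * dai +
                      y[j] * K[(size_t)t * n + j] * daj);
    ++iter;
  }

  // primal weights
  NumericVector w(d);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] == 0.0) continue;
    const double c = alpha[t] * y[t];
    for (int k = 0; k < d; ++k) w[k] += c * X(t, k);
  }

  // bias: average -y G over free SVs, else midpoint of the violation bounds
  double b = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 0 && alpha[t] < C) { b += -y[t] * G[t]; ++nfree; }
  if (nfree > 0) b /= nfree;
  else b = (Gmax + Gmin) / 2.0;

  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter, _["converged"] = converged);
}
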