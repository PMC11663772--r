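#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Compiled cores for the univariate screen (Shapiro-Wilk-gated t /
// Wilcoxon rank-sum per column) and the greedy MRMR ordering. These run
// once per inner fold of the nested LOOCV, so constant per-call overhead
// matters; the R wrappers remain the reference implementations and the
// test suite asserts equality between the two routes.

static double sw_pvalue_scalar(double W, int n) {
  double w1 = 1.0 - W;
  if (n == 3) {
    double p = 6.0 / M_PI * (std::asin(std::sqrt(W)) - std::asin(std::sqrt(0.75)));
    return std::min(std::max(p, 0.0), 1.0);
  }
  double z;
  if (n <= 11) {
    double g = -2.273 + 0.459 * n;
    double mu = 0.5440 - 0.39978 * n + 0.025054 * n * n - 0.0006714 * n * n * n;
    double sig = std::exp(1.3822 - 0.77857 * n + 0.062767 * n * n -
                          0.0020322 * n * n * n);
    z = (-std::log(g - std::log(w1)) - mu) / sig;
  } else {
    double ln = std::log((double)n);
    double mu = -1.5861 - 0.31082 * ln - 0.083751 * ln * ln +
                0.0038915 * ln * ln * ln;
    double sig = std::exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln * ln);
    z = (std::log(w1) - mu) / sig;
  }
  return R::pnorm(z, 0.0, 1.0, 0, 0);
}

// Shapiro-Wilk p for a contiguous buffer (sorted in place); a = weights
static double sw_p(std::vector<double>& v, const NumericVector& a) {
  const int n = v.size();
  std::sort(v.begin(), v.end());
  double mean = 0.0;
  for (double x : v) mean += x;
  mean /= n;
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i) {
    num += a[i] * v[i];
    den += (v[i] - mean) * (v[i] - mean);
  }
  if (den <= 0.0) return 0.0; // constant: treat as non-normal
  double W = num * num / den;
  if (!std::isfinite(W)) return 0.0;
  return sw_pvalue_scalar(W, n);
}

// [[Rcpp::export]]
List univariate_core_cpp(const NumericMatrix& X, const LogicalVector& g,
                         double alpha, const NumericVector& a1,
                         const NumericVector& a2, bool gate) {
  const int n = X.nrow(), p = X.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (g[i]) ++n1;
  const int n2 = n - n1;
  NumericVector pv(p), stat(p);
  LogicalVector is_t(p);
  std::vector<double> v1(n1), v2(n2), all(n);
  std::vector<int> idx(n);
  const double mu_u = n1 * (double)n2 / 2.0;
  for (int j = 0; j < p; ++j) {
    int k1 = 0, k2 = 0;
    for (int i = 0; i < n; ++i) {
      if (g[i]) v1[k1++] = X(i, j); else v2[k2++] = X(i, j);
    }
    bool normal = false;
    if (gate) {
      std::vector<double> s1(v1), s2(v2);
      normal = sw_p(s1, a1) > alpha && sw_p(s2, a2) > alpha;
    }
    if (normal) {
      double m1 = 0, m2 = 0;
      for (double x : v1) m1 += x;
      for (double x : v2) m2 += x;
      m1 /= n1; m2 /= n2;
      double ss = 0;
      for (double x : v1) ss += (x - m1) * (x - m1);
      for (double x : v2) ss += (x - m2) * (x - m2);
      int df = n1 + n2 - 2;
      double se = std::sqrt(ss / df * (1.0 / n1 + 1.0 / n2));
      double t = (se > 0) ? (m1 - m2) / se : 0.0;
      if (!std::isfinite(t)) t = 0.0;
      pv[j] = 2.0 * R::pt(-std::fabs(t), df, 1, 0);
      stat[j] = t;
      is_t[j] = true;
    } else {
      // Wilcoxon rank-sum, normal approximation with tie and continuity
      // corrections (matches wilcox.test(exact = FALSE, correct = TRUE))
      for (int i = 0; i < n; ++i) { all[i] = X(i, j); idx[i] = i; }
      std::sort(idx.begin(), idx.end(),
                [&](int a_, int b_) { return all[a_] < all[b_]; });
      double U = 0.0, tie_term = 0.0;
      int i = 0;
      while (i < n) {
        int k = i;
        while (k + 1 < n && all[idx[k + 1]] == all[idx[i]]) ++k;
        double r = (i + k) / 2.0 + 1.0; // average rank (1-based)
        int run = k - i + 1;
        if (run > 1) tie_term += (double)run * run * run - run;
        for (int t_ = i; t_ <= k; ++t_) if (g[idx[t_]]) U += r;
        i = k + 1;
      }
      U -= n1 * (n1 + 1.0) / 2.0;
      double sig2 = n1 * (double)n2 / 12.0 *
                    ((n + 1.0) - tie_term / ((double)n * (n - 1.0)));
      double z = 0.0;
      if (sig2 > 0) {
        double dz = U - mu_u;
        double adj = std::max(std::fabs(dz) - 0.5, 0.0);
        z = (dz > 0 ? adj : -adj) / std::sqrt(sig2);
      }
      double pp = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
      pv[j] = std::min(pp, 1.0);
      stat[j] = U - mu_u; // centred U
      is_t[j] = false;
    }
    if (!std::isfinite(pv[j])) pv[j] = 1.0;
  }
  return List::create(_["p"] = pv, _["statistic"] = stat, _["is_t"] = is_t);
}

// [[Rcpp::export]]
List mrmr_core_cpp(const NumericMatrix& X, const NumericVector& y01) {
  const int n = X.nrow(), p = X.ncol();
  // standardize columns; sd 0 -> flag
  NumericMatrix Z(n, p);
  std::vector<bool> constant(p, false);
  for (int j = 0; j < p; ++j) {
    double m = 0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    double ss = 0;
    for (int i = 0; i < n; ++i) ss += (X(i, j) - m) * (X(i, j) - m);
    double sd = std::sqrt(ss / (n - 1));
    if (sd <= 0 || !std::isfinite(sd)) { constant[j] = true; sd = 1.0; }
    for (int i = 0; i < n; ++i) Z(i, j) = (X(i, j) - m) / sd;
  }
  double my = 0;
  for (int i = 0; i < n; ++i) my += y01[i];
  my /= n;
  double ssy = 0;
  for (int i = 0; i < n; ++i) ssy += (y01[i] - my) * (y01[i] - my);
  double sdy = std::sqrt(ssy / (n - 1));
  NumericVector rel(p);
  for (int j = 0; j < p; ++j) {
    if (constant[j] || sdy <= 0) { rel[j] = 0; continue; }
    double s = 0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * (y01[i] - my) / sdy;
    rel[j] = std::fabs(s / (n - 1));
    if (!std::isfinite(rel[j])) rel[j] = 0;
  }
  // absolute correlation matrix
  NumericMatrix C(p, p);
  for (int a = 0; a < p; ++a) {
    for (int b = 0; b <= a; ++b) {
      double s = 0;
      if (!constant[a] && !constant[b])
        for (int i = 0; i < n; ++i) s += Z(i, a) * Z(i, b);
      double c = std::fabs(s / (n - 1));
      if (!std::isfinite(c)) c = 0;
      C(a, b) = c; C(b, a) = c;
    }
  }
  IntegerVector order_out(p);
  NumericVector score(p);
  std::vector<bool> chosen(p, false);
  int first = 0;
  for (int j = 1; j < p; ++j) if (rel[j] > rel[first]) first = j;
  order_out[0] = first + 1; score[0] = rel[first]; chosen[first] = true;
  std::vector<int> sel; sel.push_back(first);
  for (int step = 1; step < p; ++step) {
    int best = -1; double best_obj = -HUGE_VAL;
    for (int j = 0; j < p; ++j) {
      if (chosen[j]) continue;
      double red = 0;
      for (int s : sel) red += C(j, s);
      red /= sel.size();
      double obj = rel[j] - red;
      if (obj > best_obj) { best_obj = obj; best = j; }
    }
    order_out[step] = best + 1; score[step] = best_obj;
    chosen[best] = true; sel.push_back(best);
  }
  return List::create(_["order"] = order_out, _["score"] = score);
}
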