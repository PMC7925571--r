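#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the linear soft-margin SVM,
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)   (L1 hinge loss),
// solved in the dual (0 <= alpha_i <= C) with deterministic cyclic sweeps.
// The bias is handled by an augmented constant column appended by the caller.
// [[Rcpp::export]]
List cpp_svc_train(NumericMatrix X, NumericVector y, double C,
                   double tol = 1e-6, int max_epochs = 20000) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n, 0.0);
  const double* x = X.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = x[i + (size_t)n * j]; s += v * v; }
    qii[i] = s > 0.0 ? s : 1e-12;
  }
  int epoch = 0;
  bool converged = false;
  for (; epoch < max_epochs; ++epoch) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * x[i + (size_t)n * j];
      double G = y[i] * wx - 1.0;
      double PG;
      if (alpha[i] <= 0.0) PG = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= C) PG = G > 0.0 ? G : 0.0;
      else PG = G;
      if (std::fabs(PG) > 1e-14) {
        if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
        double old = alpha[i];
        double a = old - G / qii[i];
        if (a < 0.0) a = 0.0; else if (a > C) a = C;
        alpha[i] = a;
        double delta = (a - old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * x[i + (size_t)n * j];
      }
    }
    if (max_viol < tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch + 1,
                      _["converged"] = converged);
}

// Warm-started cost path for the classifier: solves the dual at each cost
// of an ascending grid, reusing the previous solution (feasible because the
// box only grows). Returns the weight vector (d columns) per cost.
// [[Rcpp::export]]
NumericMatrix cpp_svc_path(NumericMatrix X, NumericVector y,
                           NumericVector Cs, double tol = 1e-6,
                           int max_epochs = 20000) {
  int n = X.nrow(), d = X.ncol(), nC = Cs.size();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n, 0.0);
  const double* x = X.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = x[i + (size_t)n * j]; s += v * v; }
    qii[i] = s > 0.0 ? s : 1e-12;
  }
  NumericMatrix W(nC, d);
  for (int c = 0; c < nC; ++c) {
    double C = Cs[c];
    for (int epoch = 0; epoch < max_epochs; ++epoch) {
      double max_viol = 0.0;
      for (int i = 0; i < n; ++i) {
        double wx = 0.0;
        for (int j = 0; j < d; ++j) wx += w[j] * x[i + (size_t)n * j];
        double G = y[i] * wx - 1.0;
        double PG;
        if (alpha[i] <= 0.0) PG = G < 0.0 ? G : 0.0;
        else if (alpha[i] >= C) PG = G > 0.0 ? G : 0.0;
        else PG = G;
        if (std::fabs(PG) > 1e-14) {
          if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
          double old = alpha[i];
          double a = old - G / qii[i];
          if (a < 0.0) a = 0.0; else if (a > C) a = C;
          alpha[i] = a;
          double delta = (a - old) * y[i];
          if (delta != 0.0)
            for (int j = 0; j < d; ++j) w[j] += delta * x[i + (size_t)n * j];
        }
      }
      if (max_viol < tol) break;
    }
    for (int j = 0; j < d; ++j) W(c, j) = w[j];
  }
  return W;
}

// Dual coordinate descent for linear epsilon-insensitive support-vector
// regression (L1 loss):
//   min_w 0.5 ||w||^2 + C sum_i max(0, |y_i - w.x_i| - eps),
// dual variables beta_i in [-C, C]; same augmented-bias convention.
// [[Rcpp::export]]
List cpp_svr_train(NumericMatrix X, NumericVector y, double C,
                   double eps = 0.1, double tol = 1e-6,
                   int max_epochs = 20000) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), beta(n, 0.0), qii(n, 0.0);
  const double* x = X.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = x[i + (size_t)n * j]; s += v * v; }
    qii[i] = s > 0.0 ? s : 1e-12;
  }
  int epoch = 0;
  bool converged = false;
  for (; epoch < max_epochs; ++epoch) {
    double max_change = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * x[i + (size_t)n * j];
      double G = wx - y[i];          // gradient of the smooth part
      double Gp = G + eps, Gn = G - eps;
      double old = beta[i], nb;
      // Proximal coordinate minimization of
      //   0.5*qii*t^2 + G*t + eps*(|old + t| - |old|), box [-C, C].
      if (Gp < qii[i] * old)      nb = old - Gp / qii[i];
      else if (Gn > qii[i] * old) nb = old - Gn / qii[i];
      else                        nb = 0.0;
      if (nb < -C) nb = -C; else if (nb > C) nb = C;
      double delta = nb - old;
      if (std::fabs(delta) > 1e-14) {
        beta[i] = nb;
        if (std::fabs(delta) > max_change) max_change = std::fabs(delta);
        for (int j = 0; j < d; ++j) w[j] += delta * x[i + (size_t)n * j];
      }
    }
    if (max_change < tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["epochs"] = epoch + 1,
                      _["converged"] = converged);
}

// Warm-started cost path for the regressor (ascending costs).
// [[Rcpp::export]]
NumericMatrix cpp_svr_path(NumericMatrix X, NumericVector y,
                           NumericVector Cs, double eps = 0.1,
                           double tol = 1e-6, int max_epochs = 20000) {
  int n = X.nrow(), d = X.ncol(), nC = Cs.size();
  std::vector<double> w(d, 0.0), beta(n, 0.0), qii(n, 0.0);
  const double* x = X.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = x[i + (size_t)n * j]; s += v * v; }
    qii[i] = s > 0.0 ? s : 1e-12;
  }
  NumericMatrix W(nC, d);
  for (int c = 0; c < nC; ++c) {
    double C = Cs[c];
    for (int epoch = 0; epoch < max_epochs; ++epoch) {
      double max_change = 0.0;
      for (int i = 0; i < n; ++i) {
        double wx = 0.0;
        for (int j = 0; j < d; ++j) wx += w[j] * x[i + (size_t)n * j];
        double G = wx - y[i];
        double Gp = G + eps, Gn = G - eps;
        double old = beta[i], nb;
        if (Gp < qii[i] * old)      nb = old - Gp / qii[i];
        else if (Gn > qii[i] * old) nb = old - Gn / qii[i];
        else                        nb = 0.0;
        if (nb < -C) nb = -C; else if (nb > C) nb = C;
        double delta = nb - old;
        if (std::fabs(delta) > 1e-14) {
          beta[i] = nb;
          if (std::fabs(delta) > max_change) max_change = std::fabs(delta);
          for (int j = 0; j < d; ++j) w[j] += delta * x[i + (size_t)n * j];
        }
      }
      if (max_change < tol) break;
    }
    for (int j = 0; j < d; ++j) W(c, j) = w[j];
  }
  return W;
}
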