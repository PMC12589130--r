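// Dual coordinate descent solvers for linear support-vector models
// (LIBLINEAR-style; Hsieh et al. 2008, Ho & Lin 2012). The bias is handled by
// an augmented constant feature appended by the R wrappers. A private LCG
// drives the coordinate shuffles so results are a pure function of `seed`.

#include <Rcpp.h>
using namespace Rcpp;

static inline double lcg_next(unsigned long long &state) {
  state = state * 6364136223846793005ULL + 1442695040888963407ULL;
  return (double)((state >> 11) & 0x1FFFFFFFFFFFFFULL) / 9007199254740992.0;
}

static void shuffle_idx(std::vector<int> &idx, unsigned long long &state) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)(lcg_next(state) * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// L1-loss SVC dual CD: min 0.5*a'Qa - e'a, 0 <= a_i <= C, Q_ij=y_i y_j x_i'x_j
// [[Rcpp::export(name = ".svc_dcd")]]
List svc_dcd(NumericMatrix X, NumericVector y, double C,
             int max_epochs = 200, double tol = 1e-4, int seed = 1) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s > 1e-12 ? s : 1e-12;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long state = (unsigned long long)seed * 2654435761ULL + 1ULL;
  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    shuffle_idx(idx, state);
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / qii[i], 0.0), C);
        double d = (a_new - a_old) * y[i];
        if (d != 0.0)
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        alpha[i] = a_new;
      }
    }
    if (max_pg < tol) { ++epoch; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch);
}

// L1-loss epsilon-SVR dual CD:
// min 0.5*b'XX'b + eps*||b||_1 - y'b, -C <= b_i <= C
// [[Rcpp::export(name = ".svr_dcd")]]
List svr_dcd(NumericMatrix X, NumericVector y, double C, double eps,
             int max_epochs = 200, double tol = 1e-4, int seed = 1) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), beta(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s > 1e-12 ? s : 1e-12;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long state = (unsigned long long)seed * 40503ULL + 7ULL;
  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    shuffle_idx(idx, state);
    double max_v = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double Gq = wx - y[i];               // gradient of the quadratic part
      double Gp = Gq + eps, Gn = Gq - eps;
      double H = qii[i], b = beta[i], d;
      // exact minimizer of the piecewise quadratic along coordinate i
      if (Gp < H * b)       d = -Gp / H;
      else if (Gn > H * b)  d = -Gn / H;
      else                  d = -b;
      // projected-gradient style violation for the stop rule
      double viol;
      if (b > 0.0)      viol = std::fabs(Gp);
      else if (b < 0.0) viol = std::fabs(Gn);
      else              viol = std::max(std::max(-Gp, Gn), 0.0);
      if (b <= -C && Gn > 0.0) viol = 0.0;
      if (b >= C && Gp < 0.0) viol = 0.0;
      if (viol > max_v) max_v = viol;
      double b_new = std::min(std::max(b + d, -C), C);
      double delta = b_new - b;
      if (delta != 0.0) {
        for (int j = 0; j < p; ++j) w[j] += delta * X(i, j);
        beta[i] = b_new;
      }
    }
    if (max_v < tol) { ++epoch; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["epochs"] = epoch);
}
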