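// L2-regularized L1-loss (hinge) linear SVM solved by dual coordinate
// descent (the liblinear approach). The bias is handled as an augmented
// constant feature, and per-instance costs implement class weighting.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix X, NumericVector y, NumericVector cost,
                   int max_epoch = 1000, double tol = 1e-4, int seed = 1) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p + 1, 0.0);   // last entry: bias (augmented feature 1)
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // bias feature
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::mt19937 rng(seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epoch; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      double wx = w[p];
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= cost[i] && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_new = std::min(std::max(alpha[i] - G / qii[i], 0.0), cost[i]);
        double d = (a_new - alpha[i]) * y[i];
        alpha[i] = a_new;
        for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        w[p] += d;
      }
    }
    if (max_pg < tol) break;
  }
  NumericVector wv(p), av(n);
  for (int j = 0; j < p; ++j) wv[j] = w[j];
  for (int i = 0; i < n; ++i) av[i] = alpha[i];
  return List::create(_["w"] = wv, _["b"] = w[p], _["alpha"] = av);
}
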