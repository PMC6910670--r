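#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Full-batch gradient-descent training of a 3-layer (input, one hidden,
// output) sigmoid network with cross-entropy loss. Weights are initialized
// on the R side so that all randomness flows through R's RNG.
// W1: p x H, b1: H, w2: H, b2: scalar. Returns updated weights.
// [[Rcpp::export(name = ".nn_train_cpp")]]
List nn_train_cpp(NumericMatrix X, NumericVector y, NumericMatrix W1,
                  NumericVector b1, NumericVector w2, double b2, int epochs,
                  double lr) {
  const int n = X.nrow(), p = X.ncol(), H = W1.ncol();
  std::vector<double> a1(n * H), delta1(n * H), d2(n);
  for (int ep = 0; ep < epochs; ++ep) {
    // forward
    for (int i = 0; i < n; ++i) {
      double z2 = b2;
      for (int h = 0; h < H; ++h) {
        double z1 = b1[h];
        for (int j = 0; j < p; ++j) z1 += X(i, j) * W1(j, h);
        const double a = sigmoid(z1);
        a1[i * H + h] = a;
        z2 += a * w2[h];
      }
      d2[i] = (sigmoid(z2) - y[i]) / n;  // dL/dz2, mean cross-entropy
    }
    // backward
    for (int i = 0; i < n; ++i) {
      for (int h = 0; h < H; ++h) {
        const double a = a1[i * H + h];
        delta1[i * H + h] = d2[i] * w2[h] * a * (1.0 - a);
      }
    }
    // updates
    double gb2 = 0.0;
    for (int i = 0; i < n; ++i) gb2 += d2[i];
    for (int h = 0; h < H; ++h) {
      double gw2 = 0.0, gb1 = 0.0;
      for (int i = 0; i < n; ++i) {
        gw2 += a1[i * H + h] * d2[i];
        gb1 += delta1[i * H + h];
      }
      w2[h] -= lr * gw2;
      b1[h] -= lr * gb1;
      for (int j = 0; j < p; ++j) {
        double g = 0.0;
        for (int i = 0; i < n; ++i) g += X(i, j) * delta1[i * H + h];
        W1(j, h) -= lr * g;
      }
    }
    b2 -= lr * gb2;
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["w2"] = w2,
                      _["b2"] = b2);
}
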