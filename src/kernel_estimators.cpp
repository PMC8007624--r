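#include <Rcpp.h>
using namespace Rcpp;

// Box-kernel ("step kernel") plug-in estimators. Neighbourhoods are counted
// under the max-norm with radius r, matching a fixed-bandwidth kernel with
// Theta(|x - x_n| - r) weights; the point itself is included in every count,
// so all counts are >= 1 and the log ratios are always finite.

// Transfer entropy source -> target with unit Markov orders. a = target now,
// b = target past, c = source past (already lag-aligned by the caller).
// Returns nats.
// [[Rcpp::export]]
double kernel_te_counts(NumericVector a, NumericVector b, NumericVector c,
                        double r) {
  int n = a.size();
  long double acc = 0.0;
  for (int i = 0; i < n; i++) {
    int c_abc = 0, c_ab = 0, c_bc = 0, c_b = 0;
    double ai = a[i], bi = b[i], ci = c[i];
    for (int j = 0; j < n; j++) {
      if (std::fabs(b[j] - bi) > r) continue;
      c_b++;
      bool da = std::fabs(a[j] - ai) <= r;
      bool dc = std::fabs(c[j] - ci) <= r;
      if (da) c_ab++;
      if (dc) c_bc++;
      if (da && dc) c_abc++;
    }
    acc += std::log(((double)c_abc * (double)c_b) /
                    ((double)c_ab * (double)c_bc));
  }
  return (double)(acc / n);
}

// Mutual information between paired samples x and y (already lag-aligned).
// Returns nats.
// [[Rcpp::export]]
double kernel_mi_counts(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  long double acc = 0.0;
  for (int i = 0; i < n; i++) {
    int c_x = 0, c_y = 0, c_xy = 0;
    double xi = x[i], yi = y[i];
    for (int j = 0; j < n; j++) {
      bool dx = std::fabs(x[j] - xi) <= r;
      bool dy = std::fabs(y[j] - yi) <= r;
      if (dx) c_x++;
      if (dy) c_y++;
      if (dx && dy) c_xy++;
    }
    acc += std::log(((double)n * (double)c_xy) /
                    ((double)c_x * (double)c_y));
  }
  return (double)(acc / n);
}
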