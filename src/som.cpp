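#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen training with a Gaussian neighborhood truncated strictly
// below the current radius. The learning rate declines linearly over all
// presentations; the radius declines linearly over the first two-thirds of
// training and then holds at its end value, so a schedule ending at 1
// finishes with BMU-only (k-means-like) updates. Best-matching unit by
// minimum sum-of-squares distance; ties break to the lowest unit index, so
// training is fully deterministic given the presentation order.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix codebook0,
                   NumericMatrix grid, IntegerVector order,
                   double alpha_start, double alpha_end,
                   double radius_start, double radius_end) {
  const int d = X.ncol();
  const int U = codebook0.nrow();
  const int T = order.size();
  NumericMatrix cb = clone(codebook0);

  for (int t = 0; t < T; ++t) {
    int g = order[t] - 1;
    double frac = (T <= 1) ? 1.0 : (double) t / (double) (T - 1);
    double alpha = alpha_start + (alpha_end - alpha_start) * frac;
    double rfrac = frac * 1.5;
    if (rfrac > 1.0) rfrac = 1.0;
    double radius = radius_start + (radius_end - radius_start) * rfrac;
    if (radius < 1.0) radius = 1.0;

    int best = 0;
    double bestd = R_PosInf;
    for (int u = 0; u < U; ++u) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = X(g, j) - cb(u, j);
        s += diff * diff;
      }
      if (s < bestd) { bestd = s; best = u; }
    }

    double r2 = radius * radius;
    for (int u = 0; u < U; ++u) {
      double dr = grid(u, 0) - grid(best, 0);
      double dc = grid(u, 1) - grid(best, 1);
      double gd2 = dr * dr + dc * dc;
      if (gd2 < r2 - 1e-12) {
        double a = alpha * std::exp(-gd2 / (2.0 * r2));
        for (int j = 0; j < d; ++j)
          cb(u, j) += a * (X(g, j) - cb(u, j));
      }
    }
  }

  const int G = X.nrow();
  IntegerVector mapping(G);
  NumericVector bmu_dist(G);
  for (int g = 0; g < G; ++g) {
    int best = 0;
    double bestd = R_PosInf;
    for (int u = 0; u < U; ++u) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = X(g, j) - cb(u, j);
        s += diff * diff;
      }
      if (s < bestd) { bestd = s; best = u; }
    }
    mapping[g] = best + 1;
    bmu_dist[g] = bestd;
  }
  return List::create(_["codebook"] = cb, _["mapping"] = mapping,
                      _["bmu_dist"] = bmu_dist);
}

// Mean sum-of-squares distance from each observation to its current BMU
// (quantization error) for a fixed codebook.
// [[Rcpp::export]]
double som_qe_cpp(NumericMatrix X, NumericMatrix cb) {
  const int G = X.nrow(), d = X.ncol(), U = cb.nrow();
  double total = 0.0;
  for (int g = 0; g < G; ++g) {
    double bestd = R_PosInf;
    for (int u = 0; u < U; ++u) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = X(g, j) - cb(u, j);
        s += diff * diff;
      }
      if (s < bestd) bestd = s;
    }
    total += bestd;
  }
  return total / G;
}
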