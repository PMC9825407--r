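#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing map training on a rectangular grid.
//
// data:    cells x channels matrix (training set)
// init:    nodes x channels initial weights (one row per grid node,
//          node index = row + rows * col, column-major over the grid)
// rows, cols: grid dimensions
// order:   0-based presentation order of cells over all epochs
//          (length = cells * epochs, precomputed with R's RNG so training
//          is fully reproducible from one seed)
// alpha0, alpha1: learning rate, decayed linearly over all steps
// radius0, radius1: Gaussian neighborhood radius (grid distance units),
//          decayed linearly over all steps
//
// Returns the trained nodes x channels weight matrix.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& data,
                            const NumericMatrix& init,
                            int rows, int cols,
                            const IntegerVector& order,
                            double alpha0, double alpha1,
                            double radius0, double radius1) {
  const int n_nodes = init.nrow();
  const int p = init.ncol();
  NumericMatrix w = clone(init);
  const R_xlen_t steps = order.size();

  // grid coordinates per node
  std::vector<double> gr(n_nodes), gc(n_nodes);
  for (int k = 0; k < n_nodes; ++k) {
    gr[k] = k % rows;
    gc[k] = k / rows;
  }

  for (R_xlen_t s = 0; s < steps; ++s) {
    const int i = order[s];
    const double frac = steps > 1 ? (double)s / (double)(steps - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * frac;
    const double radius = radius0 + (radius1 - radius0) * frac;
    const double r2 = 2.0 * radius * radius;

    // best matching unit (ties -> lowest node index)
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = data(i, j) - w(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }

    for (int k = 0; k < n_nodes; ++k) {
      const double dr = gr[k] - gr[bmu];
      const double dc = gc[k] - gc[bmu];
      const double gd2 = dr * dr + dc * dc;
      double h;
      if (r2 <= 0.0) {
        h = (k == bmu) ? 1.0 : 0.0;
      } else {
        h = std::exp(-gd2 / r2);
        if (h < 1e-6) continue;
      }
      const double lr = alpha * h;
      for (int j = 0; j < p; ++j) {
        w(k, j) += lr * (data(i, j) - w(k, j));
      }
    }
  }
  return w;
}

// Nearest-node (Euclidean) assignment; ties broken by lowest node index.
// Returns 1-based node indices.
// [[Rcpp::export]]
IntegerVector nearest_node_cpp(const NumericMatrix& data,
                               const NumericMatrix& weights) {
  const int n = data.nrow();
  const int n_nodes = weights.nrow();
  const int p = weights.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = data(i, j) - weights(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    out[i] = bmu + 1;
  }
  return out;
}

// Mean cell-to-BMU Euclidean distance (quantization error).
// [[Rcpp::export]]
double quantization_error_cpp(const NumericMatrix& data,
                              const NumericMatrix& weights) {
  const int n = data.nrow();
  const int n_nodes = weights.nrow();
  const int p = weights.ncol();
  if (n == 0) return NA_REAL;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = data(i, j) - weights(k, j);
        d += diff * diff;
      }
      if (d < best) best = d;
    }
    total += std::sqrt(best);
  }
  return total / n;
}
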