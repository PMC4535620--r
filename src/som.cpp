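#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen training over genes (rows of x) with a Gaussian
// neighbourhood on a rows x cols lattice and linear decay of learning
// rate and radius.  Fully deterministic given the initial codebook and
// the presentation order (both drawn R-side).  Unit u sits at lattice
// position (u / cols, u % cols), row-major.
// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(const NumericMatrix& x, NumericMatrix codebook,
                            int rows, int cols, const IntegerVector& order,
                            double lr0, double lr1, double rad0,
                            double rad1) {
  const int d = x.ncol();
  const int m = codebook.nrow();
  const int total = order.size();
  std::vector<double> gr(m), gc(m);
  for (int u = 0; u < m; ++u) {
    gr[u] = u / cols;
    gc[u] = u % cols;
  }
  for (int t = 0; t < total; ++t) {
    const double frac = total > 1 ? (double)t / (double)(total - 1) : 0.0;
    const double lr = lr0 + (lr1 - lr0) * frac;
    const double rad = rad0 + (rad1 - rad0) * frac;
    const double denom = 2.0 * rad * rad;
    const int g = order[t];
    // best matching unit (ties -> lowest index)
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < m; ++u) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = codebook(u, j) - x(g, j);
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = u; }
    }
    // neighbourhood update
    for (int u = 0; u < m; ++u) {
      const double dr = gr[u] - gr[bmu], dc = gc[u] - gc[bmu];
      const double h = std::exp(-(dr * dr + dc * dc) / denom);
      if (h < 1e-4) continue;
      const double a = lr * h;
      for (int j = 0; j < d; ++j)
        codebook(u, j) += a * (x(g, j) - codebook(u, j));
    }
  }
  return codebook;
}

// Assign each gene to its best-matching unit (1-based; ties -> lowest
// index) and return the final quantization error as attribute "qe".
// [[Rcpp::export(name = ".som_assign_cpp")]]
IntegerVector som_assign_cpp(const NumericMatrix& x,
                             const NumericMatrix& codebook) {
  const int n = x.nrow(), d = x.ncol(), m = codebook.nrow();
  IntegerVector out(n);
  double qe = 0.0;
  for (int g = 0; g < n; ++g) {
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < m; ++u) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = codebook(u, j) - x(g, j);
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = u; }
    }
    out[g] = bmu + 1;
    qe += std::sqrt(best);
  }
  out.attr("qe") = qe / n;
  return out;
}
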