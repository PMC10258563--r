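#include <Rcpp.h>
using namespace Rcpp;

// im2col gather. H holds one batch in sample-major block layout
// (rows = (voxel, sample), cols = channel); `fill` maps H's elements into
// a flat zero-padded buffer and `gather` pulls K^3-neighbourhood columns
// out of it. Index vectors are 1-based (built in R, memoised per batch size).

// [[Rcpp::export]]
NumericMatrix conv_gather_cpp(NumericMatrix H, IntegerVector fill,
                              IntegerVector gather, double npad_total,
                              int nrow_out, int ncol_out) {
  std::vector<double> xpad((size_t)npad_total, 0.0);
  const double *h = REAL(H);
  const size_t nh = (size_t)H.nrow() * H.ncol();
  const int *fi = INTEGER(fill);
  for (size_t i = 0; i < nh; ++i) xpad[fi[i] - 1] = h[i];
  NumericMatrix A(nrow_out, ncol_out);
  double *a = REAL(A);
  const int *gi = INTEGER(gather);
  const size_t ng = (size_t)nrow_out * ncol_out;
  for (size_t i = 0; i < ng; ++i) a[i] = xpad[gi[i] - 1];
  return A;
}

// transpose of the gather: scatter-add column values back onto voxels.

// [[Rcpp::export]]
NumericMatrix conv_scatter_cpp(NumericMatrix dXcol, IntegerVector fill,
                               IntegerVector gather, double npad_total,
                               int nrow_out, int ncol_out) {
  std::vector<double> dpad((size_t)npad_total, 0.0);
  const double *d = REAL(dXcol);
  const size_t ng = (size_t)dXcol.nrow() * dXcol.ncol();
  const int *gi = INTEGER(gather);
  for (size_t i = 0; i < ng; ++i) dpad[gi[i] - 1] += d[i];
  NumericMatrix dH(nrow_out, ncol_out);
  double *out = REAL(dH);
  const int *fi = INTEGER(fill);
  const size_t nh = (size_t)nrow_out * ncol_out;
  for (size_t i = 0; i < nh; ++i) out[i] = dpad[fi[i] - 1];
  return dH;
}

// kth-nearest-neighbour Chebyshev radius in the joint (x, y) space, used
// by the KSG mutual-information estimator. Exact O(N^2) scan with an
// insertion buffer of the k smallest distances per point.

// [[Rcpp::export]]
NumericVector ksg_radius_cpp(NumericVector x, NumericVector y, int k) {
  const int N = x.size();
  NumericVector eps(N);
  std::vector<double> best(k);
  const double *px = REAL(x), *py = REAL(y);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < k; ++j) best[j] = R_PosInf;
    const double xi = px[i], yi = py[i];
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const double dx = std::fabs(px[j] - xi);
      const double dy = std::fabs(py[j] - yi);
      const double d = dx > dy ? dx : dy;
      if (d < best[k - 1]) {
        int p = k - 1;
        while (p > 0 && best[p - 1] > d) { best[p] = best[p - 1]; --p; }
        best[p] = d;
      }
    }
    eps[i] = best[k - 1];
  }
  return eps;
}
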