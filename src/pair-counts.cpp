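#include <Rcpp.h>
using namespace Rcpp;

// Ordered-pair indicator counts for every unordered gene pair {u, v}, u < v.
// For class c in {0, 1}: c<c>_lt[k] = #{samples j in class c : x[u,j] < x[v,j]},
// c<c>_gt[k] likewise for x[u,j] > x[v,j]; ties contribute to neither count.
// X is genes x samples (column-major), cls has one 0/1 label per column.
// [[Rcpp::export]]
List cpp_pair_counts(NumericMatrix x, IntegerVector cls) {
  const int m = x.nrow(), n = x.ncol();
  if (cls.size() != n) stop("labels must have one entry per sample column");
  const R_xlen_t np = (R_xlen_t)m * (m - 1) / 2;
  IntegerVector u(np), v(np), c0lt(np), c1lt(np), c0gt(np), c1gt(np);

  R_xlen_t idx = 0;
  for (int a = 0; a < m - 1; ++a)
    for (int b = a + 1; b < m; ++b, ++idx) {
      u[idx] = a + 1;
      v[idx] = b + 1;
    }

  for (int j = 0; j < n; ++j) {
    const double *col = &x(0, j);
    const int c = cls[j];
    if (c != 0 && c != 1) stop("labels must be 0 or 1");
    int *lt = (c == 0) ? c0lt.begin() : c1lt.begin();
    int *gt = (c == 0) ? c0gt.begin() : c1gt.begin();
    R_xlen_t k = 0;
    for (int a = 0; a < m - 1; ++a) {
      const double xa = col[a];
      for (int b = a + 1; b < m; ++b, ++k) {
        const double xb = col[b];
        if (xa < xb) ++lt[k];
        else if (xa > xb) ++gt[k];
      }
    }
  }

  return List::create(_["u"] = u, _["v"] = v,
                      _["c0_lt"] = c0lt, _["c1_lt"] = c1lt,
                      _["c0_gt"] = c0gt, _["c1_gt"] = c1gt);
}
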