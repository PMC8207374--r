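#include <Rcpp.h>
using namespace Rcpp;

// For each query point, is any target point within distance dd?
// Brute force with early exit; callers prune candidate targets by
// bounding circles first. Contract: identical to the O(n*m) check.
// [[Rcpp::export]]
LogicalVector cpp_any_within(NumericVector qx, NumericVector qy,
                             NumericVector tx, NumericVector ty,
                             double dd) {
  const R_xlen_t nq = qx.size(), nt = tx.size();
  const double dd2 = dd * dd;
  LogicalVector out(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    bool hit = false;
    const double xi = qx[i], yi = qy[i];
    for (R_xlen_t j = 0; j < nt; ++j) {
      const double dx = xi - tx[j], dy = yi - ty[j];
      if (dx * dx + dy * dy <= dd2) { hit = true; break; }
    }
    out[i] = hit;
  }
  return out;
}
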