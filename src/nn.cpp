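#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest neighbor between 3D point sets.
// Ties are broken by the lowest target index (strict < comparison).
// [[Rcpp::export(name = ".nn_brute")]]
List nn_brute(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow(), nt = target.nrow();
  if (nt == 0) stop("empty target point set");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  // columns are contiguous in R's column-major layout
  const double *qx = query.begin(), *qy = qx + nq, *qz = qy + nq;
  const double *tx = target.begin(), *ty = tx + nt, *tz = ty + nt;
  for (int i = 0; i < nq; ++i) {
    const double xi = qx[i], yi = qy[i], zi = qz[i];
    double best = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < nt; ++j) {
      const double dx = xi - tx[j];
      const double dy = yi - ty[j];
      const double dz = zi - tz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestj = j;
      }
    }
    idx[i] = bestj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
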