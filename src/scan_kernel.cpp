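#include <Rcpp.h>
using namespace Rcpp;

// Poisson scan log likelihood ratio for a window with (ow, ew) inside and
// totals (O, E); zero unless the inside rate exceeds the outside rate.
static inline double window_llr(double ow, double ew, double O, double E) {
  double oo = O - ow, eo = E - ew;
  if (ow * eo <= oo * ew) return 0.0;  // high-rate condition fails
  double llr = 0.0;
  if (ow > 0) llr += ow * std::log(ow / ew);
  if (oo > 0) llr += oo * std::log(oo / eo);
  return llr;
}

//' Best circular window per center over active regions.
//'
//' For every active center, walks its centroid-distance neighbor order,
//' skipping inactive (already clustered) regions, and accumulates nested
//' windows until the expected-count cap; records the maximum scan LLR and
//' the window size attaining it (first/smallest on ties).
//'
//' @param ord 1-based m x m matrix; row c lists regions by distance from c.
//' @param y,mu observed and baseline expected counts, full study area.
//' @param active logical vector; inactive regions are transparent.
//' @param cap maximum expected count inside a window.
//' @param O,E study-area totals of y and mu (not reduced by masking).
//' @return list(llr, size) per center; llr = -1 when no admissible window.
//' @noRd
// [[Rcpp::export]]
List scan_circular_best(IntegerMatrix ord, NumericVector y, NumericVector mu,
                        LogicalVector active, double cap, double O, double E) {
  const int m = ord.nrow();
  NumericVector best_llr(m, -1.0);
  IntegerVector best_size(m, 0);
  for (int c = 0; c < m; ++c) {
    if (!active[c]) continue;
    double ow = 0.0, ew = 0.0, bl = -1.0;
    int size = 0, bs = 0;
    for (int j = 0; j < m; ++j) {
      int r = ord(c, j) - 1;
      if (!active[r]) continue;
      ow += y[r];
      ew += mu[r];
      ++size;
      if (ew > cap || ew >= E) break;
      double llr = window_llr(ow, ew, O, E);
      if (llr > bl) { bl = llr; bs = size; }
    }
    best_llr[c] = bl;
    best_size[c] = bs;
  }
  return List::create(_["llr"] = best_llr, _["size"] = best_size);
}

//' Maximum circular-scan LLR for each column of a count matrix.
//'
//' Used for Monte Carlo null distributions: column r of `ymat` is one null
//' replicate; returns the full-map maximum scan LLR for each.
//'
//' @noRd
// [[Rcpp::export]]
NumericVector scan_circular_max_batch(IntegerMatrix ord, IntegerMatrix ymat,
                                      NumericVector mu, double cap, double E) {
  const int m = ord.nrow(), R = ymat.ncol();
  NumericVector out(R);
  for (int rep = 0; rep < R; ++rep) {
    double O = 0.0;
    for (int i = 0; i < m; ++i) O += ymat(i, rep);
    double best = 0.0;
    for (int c = 0; c < m; ++c) {
      double ow = 0.0, ew = 0.0;
      for (int j = 0; j < m; ++j) {
        int r = ord(c, j) - 1;
        ow += ymat(r, rep);
        ew += mu[r];
        if (ew > cap || ew >= E) break;
        double llr = window_llr(ow, ew, O, E);
        if (llr > best) best = llr;
      }
    }
    out[rep] = best;
  }
  return out;
}
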