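#include <Rcpp.h>
using namespace Rcpp;

// Sequential Bernoulli spike generation on a uniform bin grid.
//
// base_rate: K x n_trials matrix, exp(f1(t) + f3(phi_t)) in Hz evaluated at
//            bin left edges (history-free part of the intensity).
// hist_mult: length-K lookup, hist_mult[d-1] = exp(f2((d - 0.5) * delta)) for
//            a last spike d bins back (spike events live at bin centers,
//            bases are evaluated at bin left edges).
// delta:     bin width in seconds.
//
// Returns per-bin 0/1 counts and the conditional intensity actually used,
// so callers (parametric bootstrap, synchrony prediction) can reuse the
// exact lambda that generated each bin.
// [[Rcpp::export]]
List sim_binned_cpp(NumericMatrix base_rate, NumericVector hist_mult,
                    double delta) {
  int K = base_rate.nrow(), n = base_rate.ncol();
  if (hist_mult.size() < K) stop("hist_mult must have at least K entries");
  IntegerMatrix y(K, n);
  NumericMatrix lam(K, n);
  RNGScope scope;
  for (int tr = 0; tr < n; ++tr) {
    int last = -1;
    for (int k = 0; k < K; ++k) {
      double l = base_rate(k, tr);
      if (last >= 0) {
        int d = k - last;
        if (d < 1) d = 1;
        if (d > K) d = K;
        l *= hist_mult[d - 1];
      }
      lam(k, tr) = l;
      double p = l * delta;
      if (p >= 1.0)
        stop("bin spike probability >= 1 at bin %d; decrease the bin width", k + 1);
      if (unif_rand() < p) {
        y(k, tr) = 1;
        last = k;
      }
    }
  }
  return List::create(_["counts"] = y, _["lambda"] = lam);
}

// Last-spike lag per bin, in bins, from a 0/1 count matrix.  Entry (k, tr) is
// k - k_last where k_last indexes the most recent bin with a spike whose
// event time (bin center) precedes bin k's left edge, i.e. any bin < k.
// 0 marks "no history yet".
// [[Rcpp::export]]
IntegerMatrix lag_bins_cpp(IntegerMatrix counts) {
  int K = counts.nrow(), n = counts.ncol();
  IntegerMatrix lag(K, n);
  for (int tr = 0; tr < n; ++tr) {
    int last = -1;
    for (int k = 0; k < K; ++k) {
      lag(k, tr) = (last >= 0) ? (k - last) : 0;
      if (counts(k, tr) > 0) last = k;
    }
  }
  return lag;
}
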