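#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed cascade of biquads. sos: n_sections x 6
// (b0 b1 b2 a0 a1 a2), a0 assumed 1 after normalization upstream.
// [[Rcpp::export]]
NumericVector cpp_sosfilt(const NumericMatrix& sos, const NumericVector& x) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y(n);
  std::vector<double> w1(ns, 0.0), w2(ns, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double out = b0 * v + w1[s];
      w1[s] = b1 * v - a1 * out + w2[s];
      w2[s] = b2 * v - a2 * out;
      v = out;
    }
    y[i] = v;
  }
  return y;
}

// Polyphase rational resampler. h is the FIR prototype (designed at the
// upsampled rate, already scaled by L); delay centers the filter so output
// sample m corresponds to input time m*M/L. Output length supplied by caller.
// [[Rcpp::export]]
NumericVector cpp_resample_fir(const NumericVector& x, const NumericVector& h,
                               const int L, const int M, const R_xlen_t n_out,
                               const int delay) {
  const R_xlen_t n = x.size(), nh = h.size();
  NumericVector y(n_out);
  for (R_xlen_t m = 0; m < n_out; ++m) {
    const R_xlen_t t0 = m * (R_xlen_t)M + delay;
    double acc = 0.0;
    R_xlen_t k = t0 % L;
    R_xlen_t i = t0 / L;            // x index for tap k
    for (; k < nh && i >= 0; k += L, --i) {
      if (i < n) acc += h[k] * x[i];
    }
    y[m] = acc;
  }
  return y;
}

// Counts of positive pairwise spike-time lags into bins of width `bin`
// up to max_lag (seconds). Two-pointer sweep over sorted times.
// [[Rcpp::export]]
IntegerVector cpp_lag_counts(const NumericVector& t, const double bin,
                             const double max_lag) {
  const R_xlen_t n = t.size();
  const int nb = (int)std::floor(max_lag / bin);  // full-width bins only
  const double span = nb * bin;
  IntegerVector counts(nb);
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t k = i + 1; k < n; ++k) {
      const double lag = t[k] - t[i];
      if (lag >= span) break;
      const int b = (int)(lag / bin);
      if (b >= 0 && b < nb) counts[b]++;
    }
  }
  return counts;
}

// Adds a waveform template (per-channel weights x template samples) into a
// channels x time trace at given sample indices (0-based template start).
// [[Rcpp::export]]
NumericMatrix cpp_insert_spikes(NumericMatrix trace, const IntegerVector& idx,
                                const NumericVector& tmpl,
                                const NumericVector& weights) {
  const int nch = trace.nrow();
  const R_xlen_t nt = trace.ncol();
  const R_xlen_t nw = tmpl.size();
  for (R_xlen_t s = 0; s < idx.size(); ++s) {
    const R_xlen_t start = idx[s];
    for (int c = 0; c < nch; ++c) {
      const double w = weights[c];
      if (w == 0.0) continue;
      for (R_xlen_t k = 0; k < nw; ++k) {
        const R_xlen_t j = start + k;
        if (j >= 0 && j < nt) trace(c, j) += w * tmpl[k];
      }
    }
  }
  return trace;
}
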