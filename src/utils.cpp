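#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median across rows (channels) for every column (sample) of x.
// [[Rcpp::export]]
NumericVector cpp_col_medians(const NumericMatrix& x) {
  const int k = x.nrow(), n = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  const int h = k / 2;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < k; ++i) buf[i] = x(i, j);
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (k % 2 == 0) {
      const double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = 0.5 * (m + lo);
    }
    out[j] = m;
  }
  return out;
}

// Add scaled template rows into a signal matrix in place.
// sig: [channels x time]; tmpl: [channels x width]; at: 1-based start sample
// of the template for each event; amp: per-event scale; row0: 0-based first
// signal row the template maps onto.
// [[Rcpp::export]]
void cpp_add_events(NumericMatrix sig, const NumericMatrix& tmpl,
                    const IntegerVector& at, const NumericVector& amp,
                    int row0) {
  const int ch = tmpl.nrow(), n = sig.ncol(), w = tmpl.ncol();
  for (int e = 0; e < at.size(); ++e) {
    const int s0 = at[e] - 1;
    const double a = amp[e];
    for (int j = 0; j < w; ++j) {
      const int t = s0 + j;
      if (t < 0 || t >= n) continue;
      for (int c = 0; c < ch; ++c) sig(row0 + c, t) += a * tmpl(c, j);
    }
  }
}

// Across-row absolute maximum per column (detection pre-processing).
// [[Rcpp::export]]
NumericVector cpp_absmax_rows(const NumericMatrix& x) {
  const int k = x.nrow(), n = x.ncol();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double m = 0.0;
    for (int i = 0; i < k; ++i) {
      const double v = std::fabs(x(i, j));
      if (v > m) m = v;
    }
    out[j] = m;
  }
  return out;
}

// Gather fixed-length snippets around peak columns: output row e holds
// channels concatenated (channel 1 samples, channel 2 samples, ...).
// [[Rcpp::export]]
NumericMatrix cpp_gather_snippets(const NumericMatrix& x,
                                  const IntegerVector& peaks,
                                  int pre, int post) {
  const int ch = x.nrow(), w = pre + post + 1, ne = peaks.size();
  NumericMatrix out(ne, ch * w);
  for (int e = 0; e < ne; ++e) {
    const int p0 = peaks[e] - 1 - pre;
    for (int c = 0; c < ch; ++c)
      for (int j = 0; j < w; ++j)
        out(e, c * w + j) = x(c, p0 + j);
  }
  return out;
}

// Clip and quantise a [channels x time] uV matrix to interleaved int16
// ADC counts (column-major equals channel-interleaved).
// [[Rcpp::export]]
IntegerVector cpp_to_counts(const NumericMatrix& sig, double uv_per_bit) {
  const R_xlen_t n = (R_xlen_t)sig.nrow() * sig.ncol();
  IntegerVector out(n);
  const double* p = &sig(0, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = std::nearbyint(p[i] / uv_per_bit);
    if (v > 32767.0) v = 32767.0;
    if (v < -32767.0) v = -32767.0;
    out[i] = (int)v;
  }
  return out;
}
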