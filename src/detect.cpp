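#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Threshold-crossing spike detector with hysteretic re-arm.
// v: rectified across-channel maximum |voltage| per sample.
// An event opens when v >= thr while the detector is armed; it closes (and
// the detector re-arms) once v has stayed below return_thr for return_samples
// consecutive samples. The event peak is the sample maximising v.
// Returns 1-based peak sample indices.
// [[Rcpp::export]]
IntegerVector cpp_detect_peaks(const NumericVector& v, double thr,
                               double return_thr, int return_samples) {
  const int n = v.size();
  std::vector<int> peaks;
  bool in_event = false;
  int below = 0, peak_idx = -1;
  double peak_val = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!in_event) {
      if (v[i] >= thr) {
        in_event = true;
        peak_idx = i;
        peak_val = v[i];
        below = 0;
      }
    } else {
      if (v[i] > peak_val) { peak_val = v[i]; peak_idx = i; }
      if (v[i] < return_thr) {
        if (++below >= return_samples) {
          peaks.push_back(peak_idx + 1);
          in_event = false;
        }
      } else {
        below = 0;
      }
    }
  }
  if (in_event) peaks.push_back(peak_idx + 1);
  return wrap(peaks);
}

// Counts of pairwise lags (tb - ta) in bins of width binw covering
// [-(half + 0.5) * binw, (half + 0.5) * binw] around zero; bin i (1-based)
// holds lags in [(i - half - 1.5) * binw, (i - half - 0.5) * binw).
// Both trains must be sorted.
// [[Rcpp::export]]
NumericVector cpp_lag_counts(const NumericVector& ta, const NumericVector& tb,
                             double binw, int half) {
  const int nbins = 2 * half + 1;
  NumericVector counts(nbins);
  const double w = (half + 0.5) * binw;
  const int na = ta.size(), nb = tb.size();
  int lo = 0;
  for (int i = 0; i < na; ++i) {
    while (lo < nb && tb[lo] < ta[i] - w) ++lo;
    for (int j = lo; j < nb && tb[j] <= ta[i] + w; ++j) {
      const double lag = tb[j] - ta[i];
      int bin = (int)std::floor(lag / binw + 0.5) + half;
      if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
    }
  }
  return counts;
}
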