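#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// direct-form II transposed IIR; a[0] assumed 1 (caller normalises)
void iir(const std::vector<double>& b, const std::vector<double>& a,
         const double* x, double* y, int n, std::vector<double>& z) {
  const int nb = (int)b.size(), na = (int)a.size();
  const int nz = std::max(nb, na) - 1;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = (k + 1 < nb ? b[k + 1] * xi : 0.0) + z[k + 1] -
             (k + 1 < na ? a[k + 1] * yi : 0.0);
    z[nz - 1] = (nz < nb ? b[nz] * xi : 0.0) - (nz < na ? a[nz] * yi : 0.0);
    y[i] = yi;
  }
}

} // namespace

// Causal IIR filter with optional carried state (for chunked streams).
// Returns list(y, z) where z is the final filter state.
// [[Rcpp::export]]
List cpp_iir(const NumericVector& b, const NumericVector& a,
             const NumericVector& x, Nullable<NumericVector> zi) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  const int nz = std::max(bb.size(), aa.size()) - 1;
  std::vector<double> z(nz, 0.0);
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    for (int k = 0; k < std::min((int)z0.size(), nz); ++k) z[k] = z0[k];
  }
  NumericVector y(x.size());
  iir(bb, aa, REAL(x), REAL(y), x.size(), z);
  return List::create(_["y"] = y, _["z"] = wrap(z));
}

// Zero-phase filtering: odd-reflection padding of 3 * (ncoef - 1) samples on
// each end, forward pass, reversed pass, trim.
// [[Rcpp::export]]
NumericVector cpp_filtfilt(const NumericVector& b, const NumericVector& a,
                           const NumericVector& x) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  const int n = x.size();
  const int pad = 3 * ((int)std::max(bb.size(), aa.size()) - 1);
  if (n <= pad + 1) {
    // too short for reflection padding: plain forward-backward pass
    std::vector<double> z(std::max(bb.size(), aa.size()) - 1, 0.0);
    std::vector<double> y(n), rev(n);
    iir(bb, aa, REAL(x), y.data(), n, z);
    std::reverse(y.begin(), y.end());
    std::fill(z.begin(), z.end(), 0.0);
    iir(bb, aa, y.data(), rev.data(), n, z);
    std::reverse(rev.begin(), rev.end());
    return wrap(rev);
  }
  const int m = n + 2 * pad;
  std::vector<double> ext(m);
  for (int i = 0; i < pad; ++i) ext[i] = 2 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) ext[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) ext[pad + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  std::vector<double> z(std::max(bb.size(), aa.size()) - 1, 0.0);
  std::vector<double> y(m);
  iir(bb, aa, ext.data(), y.data(), m, z);
  std::reverse(y.begin(), y.end());
  std::fill(z.begin(), z.end(), 0.0);
  iir(bb, aa, y.data(), ext.data(), m, z);
  std::reverse(ext.begin(), ext.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ext[pad + i];
  return out;
}

// Median absolute deviation (unscaled).
// [[Rcpp::export]]
double cpp_mad(const NumericVector& x) {
  const int n = x.size();
  if (n == 0) return NA_REAL;
  std::vector<double> buf(x.begin(), x.end());
  auto med_of = [](std::vector<double>& v) {
    const size_t h = v.size() / 2;
    std::nth_element(v.begin(), v.begin() + h, v.end());
    double m = v[h];
    if (v.size() % 2 == 0) {
      m = 0.5 * (m + *std::max_element(v.begin(), v.begin() + h));
    }
    return m;
  };
  const double med = med_of(buf);
  for (int i = 0; i < n; ++i) buf[i] = std::fabs(x[i] - med);
  return med_of(buf);
}

// Band-limited Gaussian noise: `n` standard normals (xoshiro256+ generator
// seeded by `seed`, Box-Muller) pushed through the IIR filter with carried
// state. Returns the filtered chunk and the final state.
// [[Rcpp::export]]
List cpp_noise_chunk(double seed, int n, const NumericVector& b,
                     const NumericVector& a, const NumericVector& zi,
                     double scale) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  const int nz = std::max(bb.size(), aa.size()) - 1;
  std::vector<double> z(nz, 0.0);
  for (int k = 0; k < std::min((int)zi.size(), nz); ++k) z[k] = zi[k];

  // xoshiro256+ seeded via splitmix64
  uint64_t s[4];
  uint64_t x = (uint64_t)seed;
  for (int i = 0; i < 4; ++i) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t t = x;
    t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
    t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
    s[i] = t ^ (t >> 31);
  }
  auto nxt = [&]() {
    const uint64_t r = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return r;
  };
  auto unif = [&]() { return ((nxt() >> 11) + 0.5) * 0x1.0p-53; };

  NumericVector y(n);
  std::vector<double> white(n);
  for (int i = 0; i < n; i += 2) {
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    white[i] = r * std::cos(2.0 * M_PI * u2);
    if (i + 1 < n) white[i + 1] = r * std::sin(2.0 * M_PI * u2);
  }
  for (int i = 0; i < n; ++i) {
    const double xi = white[i];
    const double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = (k + 1 < (int)bb.size() ? bb[k + 1] * xi : 0.0) + z[k + 1] -
             (k + 1 < (int)aa.size() ? aa[k + 1] * yi : 0.0);
    z[nz - 1] = (nz < (int)bb.size() ? bb[nz] * xi : 0.0) -
                (nz < (int)aa.size() ? aa[nz] * yi : 0.0);
    y[i] = yi * scale;
  }
  return List::create(_["y"] = y, _["z"] = wrap(z));
}

// Per-row MAD of a [channels x time] matrix.
// [[Rcpp::export]]
NumericVector cpp_row_mads(const NumericMatrix& x) {
  const int k = x.nrow(), n = x.ncol();
  NumericVector out(k);
  NumericVector row(n);
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < n; ++j) row[j] = x(i, j);
    out[i] = cpp_mad(row);
  }
  return out;
}
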