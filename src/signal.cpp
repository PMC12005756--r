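#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Convolve each column of X with a (normalised) kernel; at the boundaries the
// truncated kernel mass is renormalised so that flat signals stay flat.
// [[Rcpp::export]]
NumericMatrix conv_columns(const NumericMatrix& X, const NumericVector& kernel) {
  const int n = X.nrow(), m = X.ncol(), kl = kernel.size();
  const int half = kl / 2;
  NumericMatrix out(n, m);
  std::vector<double> k(kernel.begin(), kernel.end());
  for (int j = 0; j < m; ++j) {
    const double* x = &X(0, j);
    double* o = &out(0, j);
    const int lo = std::min(half, n), hi = std::max(n - half, lo);
    for (int i = 0; i < lo; ++i) {               // left boundary
      double acc = 0.0, wsum = 0.0;
      const int a = std::max(0, i - half), b = std::min(n - 1, i + half);
      for (int t = a; t <= b; ++t) { acc += k[t - i + half] * x[t]; wsum += k[t - i + half]; }
      o[i] = wsum > 0 ? acc / wsum : 0.0;
    }
    for (int i = lo; i < hi; ++i) {              // interior, full kernel
      double acc = 0.0;
      const double* xs = x + i - half;
      for (int t = 0; t < kl; ++t) acc += k[t] * xs[t];
      o[i] = acc;
    }
    for (int i = hi; i < n; ++i) {               // right boundary
      double acc = 0.0, wsum = 0.0;
      const int a = std::max(0, i - half), b = std::min(n - 1, i + half);
      for (int t = a; t <= b; ++t) { acc += k[t - i + half] * x[t]; wsum += k[t - i + half]; }
      o[i] = wsum > 0 ? acc / wsum : 0.0;
    }
  }
  return out;
}

// Running extreme over a centred window of w = 2*half+1 points by the
// van Herk/Gil-Werman scheme: per block of w points keep suffix and prefix
// extrema, then each window extreme is the combination of two lookups.
static void running_extreme(const double* x, double* out, int n, int half,
                            bool maximum) {
  const int w = 2 * half + 1;
  std::vector<double> pre(n), suf(n);
  for (int start = 0; start < n; start += w) {
    const int end = std::min(start + w, n);
    pre[start] = x[start];
    for (int i = start + 1; i < end; ++i)
      pre[i] = maximum ? std::max(pre[i - 1], x[i]) : std::min(pre[i - 1], x[i]);
    suf[end - 1] = x[end - 1];
    for (int i = end - 2; i >= start; --i)
      suf[i] = maximum ? std::max(suf[i + 1], x[i]) : std::min(suf[i + 1], x[i]);
  }
  for (int i = 0; i < n; ++i) {
    const int a = i - half, b = std::min(i + half, n - 1);
    if (a < 0) out[i] = pre[b];  // b < w: first block covers [0, b]
    else out[i] = maximum ? std::max(suf[a], pre[b]) : std::min(suf[a], pre[b]);
  }
}

// Morphological opening (erosion then dilation with a flat structuring
// element of half-width `half` grid points) of each column; this is the
// Tophat baseline estimate.
// [[Rcpp::export]]
NumericMatrix opening_columns(const NumericMatrix& X, int half) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  std::vector<double> er(n);
  for (int j = 0; j < m; ++j) {
    running_extreme(&X(0, j), er.data(), n, half, false);
    running_extreme(er.data(), &out(0, j), n, half, true);
  }
  return out;
}
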