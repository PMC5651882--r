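#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Deposit per-scatterer response kernels into an RF frame.
//
// Each scatterer s has a fractional axial sample position pos_samp[s]
// (two-way travel time x sampling rate), a fractional lateral line position
// line_pos[s], an amplitude amp[s], and a kernel column kidx[s] (1-based)
// selecting its precomputed zero-phase impulse response (pulse x frequency
// response x path attenuation). The kernel is spread laterally with a
// Gaussian beam profile of width sigma_lines (in line pitches) and placed
// axially by linear-interpolation splitting between adjacent samples.
// [[Rcpp::export]]
NumericMatrix rf_synth(int n_ax, int n_lines,
                       NumericVector pos_samp, NumericVector line_pos,
                       NumericVector amp, IntegerVector kidx,
                       NumericMatrix kernels, int kernel_centre,
                       double sigma_lines, int max_off) {
  NumericMatrix out(n_ax, n_lines);
  const int ns = pos_samp.size();
  const int klen = kernels.nrow();
  const double inv2s2 = 1.0 / (2.0 * sigma_lines * sigma_lines);

  for (int s = 0; s < ns; ++s) {
    const double lp = line_pos[s];
    const int l_lo = std::max(0, (int)std::ceil(lp - max_off));
    const int l_hi = std::min(n_lines - 1, (int)std::floor(lp + max_off));
    if (l_lo > l_hi) continue;
    const double base = pos_samp[s] - kernel_centre;
    const int i0 = (int)std::floor(base);
    const double frac = base - i0;
    if (i0 + klen < 0 || i0 >= n_ax) continue;
    const double* kc = &kernels(0, kidx[s] - 1);
    const double a = amp[s];
    for (int l = l_lo; l <= l_hi; ++l) {
      const double d = l - lp;
      const double w = a * std::exp(-d * d * inv2s2);
      double* col = &out(0, l);
      for (int t = 0; t < klen; ++t) {
        const int idx = i0 + t;
        if (idx < 0 || idx + 1 >= n_ax) continue;
        const double v = w * kc[t];
        col[idx]     += v * (1.0 - frac);
        col[idx + 1] += v * frac;
      }
    }
  }
  return out;
}

// Burg recursion applied independently to every column of x.
// Returns (order + 1) x ncol matrix: rows 1..order are the AR coefficients
// a_1..a_p of the model x_t + sum_k a_k x_{t-k} = e_t, last row the final
// prediction-error variance.
// [[Rcpp::export]]
NumericMatrix burg_columns(NumericMatrix x, int order) {
  const int n = x.nrow(), m = x.ncol();
  if (order >= n) stop("AR order must be below the segment length");
  NumericMatrix out(order + 1, m);
  std::vector<double> f(n), b(n), a(order + 1), a_prev(order + 1);

  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) { f[i] = x(i, j); b[i] = x(i, j); }
    std::fill(a.begin(), a.end(), 0.0);
    a[0] = 1.0;
    double e = 0.0;
    for (int i = 0; i < n; ++i) e += f[i] * f[i];
    e /= n;
    for (int k = 1; k <= order; ++k) {
      // reflection coefficient from forward/backward prediction errors
      double num = 0.0, den = 0.0;
      for (int i = k; i < n; ++i) {
        num += f[i] * b[i - 1];
        den += f[i] * f[i] + b[i - 1] * b[i - 1];
      }
      double kref = (den > 0.0) ? (-2.0 * num / den) : 0.0;
      a_prev = a;
      for (int i = 1; i <= k; ++i) a[i] = a_prev[i] + kref * a_prev[k - i];
      for (int i = n - 1; i >= k; --i) {
        double fi = f[i], bim = b[i - 1];
        f[i] = fi + kref * bim;
        b[i] = bim + kref * fi;
      }
      e *= (1.0 - kref * kref);
    }
    for (int k = 1; k <= order; ++k) out(k - 1, j) = a[k];
    out(order, j) = e;
  }
  return out;
}
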