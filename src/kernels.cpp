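#include <Rcpp.h>
using namespace Rcpp;

// Gaussian kernel helpers. Densities are per-bp (1D) or per-bp^2 (2D).
// 1D evaluations assume `xs` sorted ascending so each query only touches
// points within the truncation radius (8 sd) via binary search.

static const double SQRT2PI = 2.5066282746310002;

// [[Rcpp::export]]
NumericVector cpp_kde1d(NumericVector xs, NumericVector ws, double h,
                        NumericVector q) {
  const int n = xs.size(), m = q.size();
  NumericVector out(m);
  const double cut = 8.0 * h;
  const double norm = 1.0 / (h * SQRT2PI);
  for (int k = 0; k < m; ++k) {
    const double lo = q[k] - cut, hi = q[k] + cut;
    int i0 = std::lower_bound(xs.begin(), xs.end(), lo) - xs.begin();
    double acc = 0.0;
    for (int i = i0; i < n && xs[i] <= hi; ++i) {
      const double z = (q[k] - xs[i]) / h;
      acc += ws[i] * std::exp(-0.5 * z * z);
    }
    out[k] = acc * norm;
  }
  return out;
}

// Least-squares CV criterion for an unweighted 1D Gaussian KDE:
//   LSCV(h) = (1/(n^2 h)) sum_{i,j} (K*K)((xi-xj)/h)
//           - 2/(n (n-1) h) sum_{i != j} K((xi-xj)/h)
// with (K*K)(u) = exp(-u^2/4) / (2 sqrt(pi)).
// [[Rcpp::export]]
NumericVector cpp_lscv1d(NumericVector xs, NumericVector hs) {
  const int n = xs.size(), nh = hs.size();
  NumericVector out(nh);
  for (int t = 0; t < nh; ++t) {
    const double h = hs[t];
    const double cut = 12.0 * h;
    double conv = 0.0, loo = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double d = xs[j] - xs[i];
        if (d > cut) break;
        const double u = d / h;
        conv += 2.0 * std::exp(-0.25 * u * u);
        loo += 2.0 * std::exp(-0.5 * u * u);
      }
    }
    conv += n; // diagonal terms, (K*K)(0) relative weight 1
    const double sqpi = 1.7724538509055159;
    out[t] = conv / (n * (double)n * h * 2.0 * sqpi) -
             2.0 * loo / (n * (double)(n - 1) * h * SQRT2PI);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kde2d(NumericVector px, NumericVector py, NumericVector ws,
                        double h, NumericVector qx, NumericVector qy) {
  const int n = px.size(), m = qx.size();
  NumericVector out(m);
  const double norm = 1.0 / (2.0 * M_PI * h * h);
  for (int k = 0; k < m; ++k) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = (qx[k] - px[i]) / h, dy = (qy[k] - py[i]) / h;
      const double s2 = dx * dx + dy * dy;
      if (s2 < 128.0) acc += ws[i] * std::exp(-0.5 * s2);
    }
    out[k] = acc * norm;
  }
  return out;
}

// Weighted LSCV criterion for a 2D Gaussian KDE with weights w (>= 0):
//   crit(h) = sum_{i,j} wt_i wt_j G_{sqrt(2) h}(ri - rj)
//           - 2 sum_i wt_i sum_{j != i} w_j / (W - w_i) * G_h(ri - rj)
// where wt = w / W, W = sum w, and G_s the isotropic bivariate Gaussian.
// Reduces to the standard unweighted LSCV when all weights are equal.
// [[Rcpp::export]]
NumericVector cpp_lscv2d_weighted(NumericVector px, NumericVector py,
                                  NumericVector w, NumericVector hs) {
  const int n = px.size(), nh = hs.size();
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += w[i];
  NumericVector out(nh);
  for (int t = 0; t < nh; ++t) {
    const double h = hs[t];
    const double h2 = h * h;
    double conv = 0.0, loo = 0.0;
    for (int i = 0; i < n; ++i) {
      const double wi = w[i] / W;
      const double denom_i = W - w[i];
      for (int j = 0; j < n; ++j) {
        const double dx = px[i] - px[j], dy = py[i] - py[j];
        const double s2 = (dx * dx + dy * dy) / h2;
        if (s2 > 512.0) continue;
        conv += wi * (w[j] / W) * std::exp(-0.25 * s2);
        if (j != i && denom_i > 0)
          loo += wi * (w[j] / denom_i) * std::exp(-0.5 * s2);
      }
    }
    out[t] = conv / (4.0 * M_PI * h2) - 2.0 * loo / (2.0 * M_PI * h2);
  }
  return out;
}

// Deposit weighted bivariate Gaussian kernels onto a band grid.
// Rows index window bins x_i = win_start + i * step (lower pair coordinate),
// columns index span a = 0..n_span so the cell covers (x_i, x_i + a * step).
// Cell values are kernel mass per cell (density * step^2).
// [[Rcpp::export]]
NumericMatrix cpp_kde_band(NumericVector px, NumericVector py,
                           NumericVector ws, double h, double win_start,
                           double step, int n_bins, int n_span) {
  NumericMatrix out(n_bins, n_span + 1);
  const int npair = px.size();
  const double norm = step * step / (2.0 * M_PI * h * h);
  const double cut = 6.0 * h;
  for (int k = 0; k < npair; ++k) {
    if (ws[k] <= 0) continue;
    int i_lo = (int)std::ceil((px[k] - cut - win_start) / step);
    int i_hi = (int)std::floor((px[k] + cut - win_start) / step);
    if (i_lo < 0) i_lo = 0;
    if (i_hi > n_bins - 1) i_hi = n_bins - 1;
    for (int i = i_lo; i <= i_hi; ++i) {
      const double x = win_start + i * step;
      const double dx = (x - px[k]) / h;
      int a_lo = (int)std::ceil((py[k] - cut - x) / step);
      int a_hi = (int)std::floor((py[k] + cut - x) / step);
      if (a_lo < 0) a_lo = 0;
      if (a_hi > n_span) a_hi = n_span;
      for (int a = a_lo; a <= a_hi; ++a) {
        const double dy = (x + a * step - py[k]) / h;
        out(i, a) += ws[k] * norm * std::exp(-0.5 * (dx * dx + dy * dy));
      }
    }
  }
  return out;
}

// Forward model: band of occ convolved with the RSF.
// rsf is a K x K matrix, K = 2*Wb + 1, entry (idx, idy) = offsets
// (idx - Wb, idy - Wb) in grid steps. M(i, a) = sum_ddx occ(i - ddx) *
// rsf(ddx + Wb, ddx + a + Wb).
// [[Rcpp::export]]
NumericMatrix cpp_band_model(NumericVector occ, NumericMatrix rsf,
                             int n_span) {
  const int n = occ.size(), K = rsf.nrow();
  const int Wb = (K - 1) / 2;
  NumericMatrix out(n, n_span + 1);
  const int amax = std::min(n_span, 2 * Wb);
  for (int a = 0; a <= amax; ++a) {
    for (int ddx = -Wb; ddx <= Wb - a; ++ddx) {
      const double kv = rsf(ddx + Wb, ddx + a + Wb);
      if (kv <= 0) continue;
      int i_lo = std::max(0, ddx), i_hi = std::min(n - 1, n - 1 + ddx);
      for (int i = i_lo; i <= i_hi; ++i) {
        out(i, a) += occ[i - ddx] * kv;
      }
    }
  }
  return out;
}

static NumericMatrix ratio_band(const NumericMatrix &band,
                                const NumericMatrix &model) {
  const int n = band.nrow(), m = band.ncol();
  NumericMatrix rat(n, m);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < m; ++a) {
      const double d = band(i, a);
      if (d <= 0) { rat(i, a) = 0.0; continue; }
      const double mm = model(i, a);
      if (mm < 1e-300)
        stop("re-blurred estimate is zero where data mass exists (bin %d, span %d)",
             i + 1, a);
      rat(i, a) = d / mm;
    }
  return rat;
}

// One multiplicative Richardson-Lucy update of the occupancy with the RSF
// held fixed; output rescaled to the input sum.
// [[Rcpp::export]]
NumericVector cpp_rl_occ(NumericVector occ, NumericMatrix rsf,
                         NumericMatrix band) {
  const int n = occ.size(), K = rsf.nrow();
  const int Wb = (K - 1) / 2, n_span = band.ncol() - 1;
  NumericMatrix model = cpp_band_model(occ, rsf, n_span);
  NumericMatrix rat = ratio_band(band, model);
  NumericVector out(n);
  const int amax = std::min(n_span, 2 * Wb);
  for (int a = 0; a <= amax; ++a) {
    for (int ddx = -Wb; ddx <= Wb - a; ++ddx) {
      const double kv = rsf(ddx + Wb, ddx + a + Wb);
      if (kv <= 0) continue;
      for (int j = 0; j < n; ++j) {
        const int i = j + ddx;
        if (i < 0 || i >= n) continue;
        out[j] += rat(i, a) * kv;
      }
    }
  }
  double s_in = 0.0, s_out = 0.0;
  for (int j = 0; j < n; ++j) {
    out[j] *= occ[j];
    s_in += occ[j];
    s_out += out[j];
  }
  if (s_out <= 0) stop("occupancy update collapsed to zero mass");
  for (int j = 0; j < n; ++j) out[j] *= s_in / s_out;
  return out;
}

// One multiplicative update of the RSF with the occupancy held fixed
// (blind RL correlation form); output rescaled to the input sum.
// [[Rcpp::export]]
NumericMatrix cpp_rl_rsf(NumericVector occ, NumericMatrix rsf,
                         NumericMatrix band) {
  const int n = occ.size(), K = rsf.nrow();
  const int Wb = (K - 1) / 2, n_span = band.ncol() - 1;
  NumericMatrix model = cpp_band_model(occ, rsf, n_span);
  NumericMatrix rat = ratio_band(band, model);
  NumericMatrix out(K, K);
  double s_in = 0.0, s_out = 0.0;
  for (int idx = 0; idx < K; ++idx) {
    for (int idy = 0; idy < K; ++idy) {
      s_in += rsf(idx, idy);
      const int a = idy - idx;
      if (a < 0 || a > n_span || rsf(idx, idy) <= 0) continue;
      const int ddx = idx - Wb;
      double acc = 0.0;
      for (int j = 0; j < n; ++j) {
        const int i = j + ddx;
        if (i < 0 || i >= n) continue;
        acc += occ[j] * rat(i, a);
      }
      out(idx, idy) = rsf(idx, idy) * acc;
      s_out += out(idx, idy);
    }
  }
  if (s_out <= 0) stop("RSF update collapsed to zero mass");
  for (int idx = 0; idx < K; ++idx)
    for (int idy = 0; idy < K; ++idy) out(idx, idy) *= s_in / s_out;
  return out;
}
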