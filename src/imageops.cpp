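// Voxel-level image operations: separable cubic resampling, in-plane
// rotation, Gaussian smooth+subsample degradation, box-window statistics
// for SSIM, and 3D binary morphology / connected components for masking.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Keys cubic-convolution kernel, a = -0.5 (Catmull-Rom). Interpolating:
// exact on the sample grid and reproduces linear functions.
static inline double keys_w(double t) {
  t = std::fabs(t);
  const double a = -0.5;
  if (t < 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0) return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// symmetric (half-sample) reflection: ...2 1 0 | 0 1 2 ... n-1 | n-1 n-2...
static inline int reflecti(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Resample one axis of a cube with cubic convolution. Two grid mappings:
// pixel-center (src = (i+0.5)*scale - 0.5), the convention for generic
// resizing, and origin-anchored (src = i*step), the inverse of decimation
// anchored at index 0. Border taps clamp to edge.
static arma::cube resample_axis(const arma::cube& x, int axis, int n_out,
                                bool origin = false, double step = 0.0) {
  int n_in = (axis == 0) ? x.n_rows : (axis == 1) ? x.n_cols : x.n_slices;
  double scale = (double)n_in / (double)n_out;
  if (origin && step <= 0.0) step = scale;
  // precompute taps and weights per output index
  arma::imat taps(n_out, 4);
  arma::mat wts(n_out, 4);
  for (int i = 0; i < n_out; ++i) {
    double src = origin ? i * step : (i + 0.5) * scale - 0.5;
    int i0 = (int)std::floor(src);
    double fr = src - i0;
    for (int t = 0; t < 4; ++t) {
      taps(i, t) = clampi(i0 - 1 + t, n_in);
      wts(i, t) = keys_w(fr - (t - 1));
    }
    double s = arma::accu(wts.row(i));
    wts.row(i) /= s;  // renormalize (guards clamped/edge cases)
  }
  arma::uword d1 = (axis == 0) ? (arma::uword)n_out : x.n_rows;
  arma::uword d2 = (axis == 1) ? (arma::uword)n_out : x.n_cols;
  arma::uword d3 = (axis == 2) ? (arma::uword)n_out : x.n_slices;
  arma::cube y(d1, d2, d3);
  for (arma::uword k = 0; k < d3; ++k)
    for (arma::uword j = 0; j < d2; ++j)
      for (arma::uword i = 0; i < d1; ++i) {
        int o = (axis == 0) ? (int)i : (axis == 1) ? (int)j : (int)k;
        double acc = 0.0;
        for (int t = 0; t < 4; ++t) {
          int s = (int)taps(o, t);
          acc += wts(o, t) * ((axis == 0) ? x(s, j, k)
                              : (axis == 1) ? x(i, s, k)
                                            : x(i, j, s));
        }
        y(i, j, k) = acc;
      }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_cubic")]]
arma::cube cpp_resize_cubic(const arma::cube& x, int n1, int n2, int n3) {
  arma::cube y = x;
  if ((int)y.n_rows != n1) y = resample_axis(y, 0, n1);
  if ((int)y.n_cols != n2) y = resample_axis(y, 1, n2);
  if ((int)y.n_slices != n3) y = resample_axis(y, 2, n3);
  return y;
}

// origin-anchored resampling; steps give input voxels per output voxel
// (0 = proportional n_in/n_out)
// [[Rcpp::export(name = ".cpp_resize_cubic_origin")]]
arma::cube cpp_resize_cubic_origin(const arma::cube& x, int n1, int n2,
                                   int n3, double s1, double s2, double s3) {
  arma::cube y = x;
  if ((int)y.n_rows != n1 || s1 != 1.0) y = resample_axis(y, 0, n1, true, s1);
  if ((int)y.n_cols != n2 || s2 != 1.0) y = resample_axis(y, 1, n2, true, s2);
  if ((int)y.n_slices != n3 || s3 != 1.0) y = resample_axis(y, 2, n3, true, s3);
  return y;
}

// 2D cubic sample with zero outside the grid
static inline double sample2d(const arma::mat& s, double u, double v) {
  int nu = s.n_rows, nv = s.n_cols;
  if (u < -0.5 || u > nu - 0.5 || v < -0.5 || v > nv - 0.5) return 0.0;
  int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
  double fu = u - u0, fv = v - v0;
  double acc = 0.0, wsum = 0.0;
  for (int a = 0; a < 4; ++a) {
    int ui = u0 - 1 + a;
    double wu = keys_w(fu - (a - 1));
    for (int b = 0; b < 4; ++b) {
      int vi = v0 - 1 + b;
      double wv = keys_w(fv - (b - 1));
      double w = wu * wv;
      wsum += w;
      if (ui >= 0 && ui < nu && vi >= 0 && vi < nv) acc += w * s(ui, vi);
    }
  }
  (void)wsum;
  return acc;
}

// Rotate in the plane of axes (axis_a, axis_b), 0-based, about the volume
// center; cubic interpolation, zero fill outside.
// [[Rcpp::export(name = ".cpp_rotate_plane")]]
arma::cube cpp_rotate_plane(const arma::cube& x, int axis_a, int axis_b,
                            double angle_deg) {
  double th = angle_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  arma::cube y(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  int axes[3] = {0, 1, 2};
  int axis_c = axes[0] + axes[1] + axes[2] - axis_a - axis_b;
  int na = (axis_a == 0) ? x.n_rows : (axis_a == 1) ? x.n_cols : x.n_slices;
  int nb = (axis_b == 0) ? x.n_rows : (axis_b == 1) ? x.n_cols : x.n_slices;
  int nc = (axis_c == 0) ? x.n_rows : (axis_c == 1) ? x.n_cols : x.n_slices;
  double ca = (na - 1) / 2.0, cb = (nb - 1) / 2.0;
  // extract slice (a,b) at index c
  arma::mat sl(na, nb);
  arma::uvec idx(3);
  for (int c = 0; c < nc; ++c) {
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nb; ++b) {
        idx(axis_a) = a; idx(axis_b) = b; idx(axis_c) = c;
        sl(a, b) = x(idx(0), idx(1), idx(2));
      }
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nb; ++b) {
        // inverse map: source = R(-th) * (p - center) + center
        double da = a - ca, db = b - cb;
        double sa = ct * da + st * db + ca;
        double sb = -st * da + ct * db + cb;
        idx(axis_a) = a; idx(axis_b) = b; idx(axis_c) = c;
        y(idx(0), idx(1), idx(2)) = sample2d(sl, sa, sb);
      }
  }
  return y;
}

// Gaussian smoothing evaluated at strided voxels: output index k along an
// axis reads input neighborhood centered at k*N; symmetric reflection at
// borders; kernel normalized to sum 1.
// [[Rcpp::export(name = ".cpp_gauss_subsample")]]
arma::cube cpp_gauss_subsample(const arma::cube& x, int N, int ksize,
                               double sigma) {
  int h = (ksize - 1) / 2;
  arma::cube ker(ksize, ksize, ksize);
  for (int a = -h; a <= h; ++a)
    for (int b = -h; b <= h; ++b)
      for (int c = -h; c <= h; ++c)
        ker(a + h, b + h, c + h) =
            std::exp(-(a * a + b * b + c * c) / (2.0 * sigma * sigma));
  ker /= arma::accu(ker);
  int d1 = x.n_rows, d2 = x.n_cols, d3 = x.n_slices;
  int o1 = d1 / N, o2 = d2 / N, o3 = d3 / N;
  arma::cube y(o1, o2, o3);
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        double acc = 0.0;
        for (int c = -h; c <= h; ++c) {
          int kz = reflecti(k * N + c, d3);
          for (int b = -h; b <= h; ++b) {
            int ky = reflecti(j * N + b, d2);
            for (int a = -h; a <= h; ++a)
              acc += ker(a + h, b + h, c + h) *
                     x(reflecti(i * N + a, d1), ky, kz);
          }
        }
        y(i, j, k) = acc;
      }
  return y;
}

// Box-window local mean with symmetric reflection, per axis, window w (odd).
// [[Rcpp::export(name = ".cpp_box_mean")]]
arma::cube cpp_box_mean(const arma::cube& x, int w) {
  int h = (w - 1) / 2;
  arma::cube a = x, b(x.n_rows, x.n_cols, x.n_slices);
  int d1 = x.n_rows, d2 = x.n_cols, d3 = x.n_slices;
  // axis 0
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double s = 0;
        for (int t = -h; t <= h; ++t) s += a(reflecti(i + t, d1), j, k);
        b(i, j, k) = s / w;
      }
  a = b;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double s = 0;
        for (int t = -h; t <= h; ++t) s += a(i, reflecti(j + t, d2), k);
        b(i, j, k) = s / w;
      }
  a = b;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double s = 0;
        for (int t = -h; t <= h; ++t) s += a(i, j, reflecti(k + t, d3));
        b(i, j, k) = s / w;
      }
  return b;
}

// ---- binary 3D morphology and labelling (6-connectivity BFS) ----

// [[Rcpp::export(name = ".cpp_binary_dilate")]]
LogicalVector cpp_binary_dilate(LogicalVector m, IntegerVector dims, int w) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], h = (w - 1) / 2;
  LogicalVector out(m.size());
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        bool v = false;
        for (int c = -h; c <= h && !v; ++c) {
          int kk = k + c; if (kk < 0 || kk >= d3) continue;
          for (int b = -h; b <= h && !v; ++b) {
            int jj = j + b; if (jj < 0 || jj >= d2) continue;
            for (int a = -h; a <= h; ++a) {
              int ii = i + a; if (ii < 0 || ii >= d1) continue;
              if (m[ii + d1 * (jj + (R_xlen_t)d2 * kk)]) { v = true; break; }
            }
          }
        }
        out[i + d1 * (j + (R_xlen_t)d2 * k)] = v;
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_binary_erode")]]
LogicalVector cpp_binary_erode(LogicalVector m, IntegerVector dims, int w) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], h = (w - 1) / 2;
  LogicalVector out(m.size());
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        bool v = true;
        for (int c = -h; c <= h && v; ++c) {
          int kk = k + c;
          for (int b = -h; b <= h && v; ++b) {
            int jj = j + b;
            for (int a = -h; a <= h; ++a) {
              int ii = i + a;
              bool in = (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 &&
                         kk >= 0 && kk < d3);
              // outside the grid counts as background
              if (!in || !m[ii + d1 * (jj + (R_xlen_t)d2 * kk)]) { v = false; break; }
            }
          }
        }
        out[i + d1 * (j + (R_xlen_t)d2 * k)] = v;
      }
  return out;
}

// Largest 6-connected foreground component.
// [[Rcpp::export(name = ".cpp_largest_component")]]
LogicalVector cpp_largest_component(LogicalVector m, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = m.size();
  std::vector<int> lab(n, 0);
  int cur = 0; R_xlen_t best_size = 0; int best_lab = 0;
  std::vector<R_xlen_t> stack;
  const int off1[6] = {-1, 1, 0, 0, 0, 0};
  const int off2[6] = {0, 0, -1, 1, 0, 0};
  const int off3[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++cur;
    R_xlen_t size = 0;
    stack.clear(); stack.push_back(s); lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back(); ++size;
      int i = v % d1, j = (v / d1) % d2, k = v / ((R_xlen_t)d1 * d2);
      for (int t = 0; t < 6; ++t) {
        int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t u = ii + d1 * (jj + (R_xlen_t)d2 * kk);
        if (m[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
      }
    }
    if (size > best_size) { best_size = size; best_lab = cur; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (lab[s] == best_lab);
  return out;
}

// Fill holes: background voxels not 6-connected to the border become tissue.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
LogicalVector cpp_fill_holes(LogicalVector m, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = m.size();
  std::vector<char> reach(n, 0);
  std::vector<R_xlen_t> stack;
  const int off1[6] = {-1, 1, 0, 0, 0, 0};
  const int off2[6] = {0, 0, -1, 1, 0, 0};
  const int off3[6] = {0, 0, 0, 0, -1, 1};
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        if (i > 0 && i < d1 - 1 && j > 0 && j < d2 - 1 && k > 0 && k < d3 - 1)
          continue;
        R_xlen_t v = i + d1 * (j + (R_xlen_t)d2 * k);
        if (!m[v] && !reach[v]) { reach[v] = 1; stack.push_back(v); }
      }
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int i = v % d1, j = (v / d1) % d2, k = v / ((R_xlen_t)d1 * d2);
    for (int t = 0; t < 6; ++t) {
      int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
        continue;
      R_xlen_t u = ii + d1 * (jj + (R_xlen_t)d2 * kk);
      if (!m[u] && !reach[u]) { reach[u] = 1; stack.push_back(u); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = m[s] || !reach[s];
  return out;
}

// Masked L1 + masked forward-difference gradient L1, double precision.
// MAE term averages |pred-target| over mask voxels; gradient term averages
// |d(pred)-d(target)| over all (axis, position) stencils whose two voxels
// are both tissue. Empty mask (or no valid stencil) contributes 0.
// [[Rcpp::export(name = ".cpp_l1grad_loss")]]
double cpp_l1grad_loss(const arma::cube& pred, const arma::cube& target,
                       const arma::cube& mask) {
  int d1 = pred.n_rows, d2 = pred.n_cols, d3 = pred.n_slices;
  double s_mae = 0.0; R_xlen_t n_mae = 0;
  double s_g = 0.0; R_xlen_t n_g = 0;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        if (mask(i, j, k) == 0) continue;
        ++n_mae;
        s_mae += std::fabs(pred(i, j, k) - target(i, j, k));
        if (i + 1 < d1 && mask(i + 1, j, k) != 0) {
          ++n_g;
          s_g += std::fabs((pred(i + 1, j, k) - pred(i, j, k)) -
                           (target(i + 1, j, k) - target(i, j, k)));
        }
        if (j + 1 < d2 && mask(i, j + 1, k) != 0) {
          ++n_g;
          s_g += std::fabs((pred(i, j + 1, k) - pred(i, j, k)) -
                           (target(i, j + 1, k) - target(i, j, k)));
        }
        if (k + 1 < d3 && mask(i, j, k + 1) != 0) {
          ++n_g;
          s_g += std::fabs((pred(i, j, k + 1) - pred(i, j, k)) -
                           (target(i, j, k + 1) - target(i, j, k)));
        }
      }
  double L = 0.0;
  if (n_mae > 0) L += s_mae / (double)n_mae;
  if (n_g > 0) L += s_g / (double)n_g;
  return L;
}
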