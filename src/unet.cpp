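// Residual U-Net engine: im2col/GEMM convolutions, batch norm, max pooling,
// transposed convolutions, skip concatenation, 1x1 residual projections,
// sigmoid head, masked L1+gradient loss, and Adam — float32 throughout.
// Feature maps are (channels x batch*voxels) matrices, voxels in R array
// order (first dimension fastest), samples in contiguous column blocks.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Dims {
  int d[3];
  long V() const { return (long)d[0] * d[1] * d[2]; }
};

static const float ADAM_B1 = 0.9f, ADAM_B2 = 0.999f, ADAM_EPS = 1e-8f;

struct Param {
  fmat val, g, m, v;
  void init(int r, int c) {
    val.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void step(float lr, int t) {
    m = ADAM_B1 * m + (1.0f - ADAM_B1) * g;
    v = ADAM_B2 * v + (1.0f - ADAM_B2) * (g % g);
    float c1 = 1.0f - std::pow(ADAM_B1, (float)t);
    float c2 = 1.0f - std::pow(ADAM_B2, (float)t);
    val -= lr * (m / c1) / (arma::sqrt(v / c2) + ADAM_EPS);
  }
};

// ---------- im2col / col2im with zero 'same' padding ----------

// per-offset column shift and spatial validity, precomputed once
struct KernelMap {
  std::vector<long> delta;
  std::vector<int> oa, ob, oc;
  int K;
  KernelMap(Dims dm, const int k[3]) {
    K = k[0] * k[1] * k[2];
    delta.resize(K); oa.resize(K); ob.resize(K); oc.resize(K);
    int p0 = k[0] / 2, p1 = k[1] / 2, p2 = k[2] / 2, t = 0;
    for (int dc = 0; dc < k[2]; ++dc)
      for (int db = 0; db < k[1]; ++db)
        for (int da = 0; da < k[0]; ++da, ++t) {
          oa[t] = da - p0; ob[t] = db - p1; oc[t] = dc - p2;
          delta[t] = oa[t] + (long)dm.d[0] * (ob[t] + (long)dm.d[1] * oc[t]);
        }
  }
};

// Direct 'same' convolution (zero padding). Channel dimensions are the
// contiguous axis of every feature matrix and of the weight columns; the
// kernels are templated on that width so the inner loops unroll into
// register-resident vector accumulators, with runtime dispatch to an
// AVX2/FMA clone where the CPU supports it.
#if defined(__x86_64__) && defined(__gnu_linux__)
#define VOXSR_CLONES __attribute__((target_clones("arch=x86-64-v3", "default")))
#else
#define VOXSR_CLONES
#endif

// The hot loops process interior runs of 4 voxels along the first axis at
// once: four accumulator banks share every weight load, breaking the FMA
// dependency chain. Boundary voxels fall back to the per-voxel path.

template <int F>
static inline void conv_fwd_voxel(const fmat& X, const float* wp,
                                  const float* bp, Dims dm,
                                  const KernelMap& km, int C, int x, int y,
                                  int z, long v, fmat& Y) {
  float acc[F];
  for (int f = 0; f < F; ++f) acc[f] = bp[f];
  for (int t = 0; t < km.K; ++t) {
    const int xx = x + km.oa[t];
    if (xx < 0 || xx >= dm.d[0]) continue;
    const int yy = y + km.ob[t];
    if (yy < 0 || yy >= dm.d[1]) continue;
    const int zz = z + km.oc[t];
    if (zz < 0 || zz >= dm.d[2]) continue;
    const float* xc = X.colptr(v + km.delta[t]);
    const float* wt = wp + (size_t)t * C * F;
    for (int c = 0; c < C; ++c) {
      const float xv = xc[c];
      const float* wc = wt + (size_t)c * F;
      for (int f = 0; f < F; ++f) acc[f] += wc[f] * xv;
    }
  }
  float* yc = Y.colptr(v);
  for (int f = 0; f < F; ++f) yc[f] = acc[f];
}

template <int F>
VOXSR_CLONES
static void conv_fwd_tpl(const fmat& X, const fmat& W, const fmat& bias,
                         Dims dm, int B, const KernelMap& km, fmat& Y) {
  const int C = X.n_rows, K = km.K;
  const long V = dm.V();
  const int d0 = dm.d[0], p0 = (d0 > 1) ? 1 : 0;
  const float* wp = W.memptr();
  const float* bp = bias.memptr();
  std::vector<int> tv(K);
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y) {
        const long row = base + (long)d0 * (y + (long)dm.d[1] * z);
        int ntv = 0;
        for (int t = 0; t < K; ++t) {
          const int yy = y + km.ob[t], zz = z + km.oc[t];
          if (yy >= 0 && yy < dm.d[1] && zz >= 0 && zz < dm.d[2])
            tv[ntv++] = t;
        }
        int x = 0;
        for (; x < p0; ++x)
          conv_fwd_voxel<F>(X, wp, bp, dm, km, C, x, y, z, row + x, Y);
        const int xin = d0 - p0;
        for (; x + 3 < xin; x += 4) {
          const long v = row + x;
          float a0[F], a1[F], a2[F], a3[F];
          for (int f = 0; f < F; ++f) a0[f] = a1[f] = a2[f] = a3[f] = bp[f];
          for (int it = 0; it < ntv; ++it) {
            const int t = tv[it];
            const float* xc = X.colptr(v + km.delta[t]);
            const float* wt = wp + (size_t)t * C * F;
            for (int c = 0; c < C; ++c) {
              const float x0 = xc[c], x1 = xc[C + c], x2 = xc[2 * C + c],
                          x3 = xc[3 * C + c];
              const float* wc = wt + (size_t)c * F;
              for (int f = 0; f < F; ++f) {
                const float w = wc[f];
                a0[f] += w * x0; a1[f] += w * x1;
                a2[f] += w * x2; a3[f] += w * x3;
              }
            }
          }
          float* yc = Y.colptr(v);
          for (int f = 0; f < F; ++f) yc[f] = a0[f];
          for (int f = 0; f < F; ++f) yc[F + f] = a1[f];
          for (int f = 0; f < F; ++f) yc[2 * F + f] = a2[f];
          for (int f = 0; f < F; ++f) yc[3 * F + f] = a3[f];
        }
        for (; x < d0; ++x)
          conv_fwd_voxel<F>(X, wp, bp, dm, km, C, x, y, z, row + x, Y);
      }
  }
}

template <int F, int CT>
VOXSR_CLONES
static void conv_fwd_tpl2(const fmat& X, const fmat& W, const fmat& bias,
                         Dims dm, int B, const KernelMap& km, fmat& Y) {
  const int C = CT; const int K = km.K;
  const long V = dm.V();
  const int d0 = dm.d[0], p0 = (d0 > 1) ? 1 : 0;
  const float* wp = W.memptr();
  const float* bp = bias.memptr();
  std::vector<int> tv(K);
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y) {
        const long row = base + (long)d0 * (y + (long)dm.d[1] * z);
        int ntv = 0;
        for (int t = 0; t < K; ++t) {
          const int yy = y + km.ob[t], zz = z + km.oc[t];
          if (yy >= 0 && yy < dm.d[1] && zz >= 0 && zz < dm.d[2])
            tv[ntv++] = t;
        }
        int x = 0;
        for (; x < p0; ++x)
          conv_fwd_voxel<F>(X, wp, bp, dm, km, C, x, y, z, row + x, Y);
        const int xin = d0 - p0;
        for (; x + 3 < xin; x += 4) {
          const long v = row + x;
          float a0[F], a1[F], a2[F], a3[F];
          for (int f = 0; f < F; ++f) a0[f] = a1[f] = a2[f] = a3[f] = bp[f];
          for (int it = 0; it < ntv; ++it) {
            const int t = tv[it];
            const float* xc = X.colptr(v + km.delta[t]);
            const float* wt = wp + (size_t)t * C * F;
            for (int c = 0; c < C; ++c) {
              const float x0 = xc[c], x1 = xc[C + c], x2 = xc[2 * C + c],
                          x3 = xc[3 * C + c];
              const float* wc = wt + (size_t)c * F;
              for (int f = 0; f < F; ++f) {
                const float w = wc[f];
                a0[f] += w * x0; a1[f] += w * x1;
                a2[f] += w * x2; a3[f] += w * x3;
              }
            }
          }
          float* yc = Y.colptr(v);
          for (int f = 0; f < F; ++f) yc[f] = a0[f];
          for (int f = 0; f < F; ++f) yc[F + f] = a1[f];
          for (int f = 0; f < F; ++f) yc[2 * F + f] = a2[f];
          for (int f = 0; f < F; ++f) yc[3 * F + f] = a3[f];
        }
        for (; x < d0; ++x)
          conv_fwd_voxel<F>(X, wp, bp, dm, km, C, x, y, z, row + x, Y);
      }
  }
}

template <int C>
static inline void conv_dx_voxel(const fmat& dY, const float* wp, Dims dm,
                                 const KernelMap& km, int F, int x, int y,
                                 int z, long v, fmat& dX) {
  float acc[C];
  for (int c = 0; c < C; ++c) acc[c] = 0.0f;
  for (int t = 0; t < km.K; ++t) {
    const int xx = x - km.oa[t];
    if (xx < 0 || xx >= dm.d[0]) continue;
    const int yy = y - km.ob[t];
    if (yy < 0 || yy >= dm.d[1]) continue;
    const int zz = z - km.oc[t];
    if (zz < 0 || zz >= dm.d[2]) continue;
    const float* dyc = dY.colptr(v - km.delta[t]);
    const float* wt = wp + (size_t)t * F * C;
    for (int f = 0; f < F; ++f) {
      const float dv = dyc[f];
      const float* wc = wt + (size_t)f * C;
      for (int c = 0; c < C; ++c) acc[c] += wc[c] * dv;
    }
  }
  float* dxc = dX.colptr(v);
  for (int c = 0; c < C; ++c) dxc[c] = acc[c];
}

template <int C>
VOXSR_CLONES
static void conv_bwd_dx_tpl(const fmat& dY, const fmat& WT, Dims dm, int B,
                            const KernelMap& km, fmat& dX) {
  const int F = dY.n_rows, K = km.K;
  const long V = dm.V();
  const int d0 = dm.d[0], p0 = (d0 > 1) ? 1 : 0;
  const float* wp = WT.memptr();
  std::vector<int> tv(K);
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y) {
        const long row = base + (long)d0 * (y + (long)dm.d[1] * z);
        int ntv = 0;
        for (int t = 0; t < K; ++t) {
          const int yy = y - km.ob[t], zz = z - km.oc[t];
          if (yy >= 0 && yy < dm.d[1] && zz >= 0 && zz < dm.d[2])
            tv[ntv++] = t;
        }
        int x = 0;
        for (; x < p0; ++x)
          conv_dx_voxel<C>(dY, wp, dm, km, F, x, y, z, row + x, dX);
        const int xin = d0 - p0;
        for (; x + 3 < xin; x += 4) {
          const long v = row + x;
          float a0[C], a1[C], a2[C], a3[C];
          for (int c = 0; c < C; ++c) a0[c] = a1[c] = a2[c] = a3[c] = 0.0f;
          for (int it = 0; it < ntv; ++it) {
            const int t = tv[it];
            const float* dyc = dY.colptr(v - km.delta[t]);
            const float* wt = wp + (size_t)t * F * C;
            for (int f = 0; f < F; ++f) {
              const float d0v = dyc[f], d1v = dyc[F + f],
                          d2v = dyc[2 * F + f], d3v = dyc[3 * F + f];
              const float* wc = wt + (size_t)f * C;
              for (int c = 0; c < C; ++c) {
                const float w = wc[c];
                a0[c] += w * d0v; a1[c] += w * d1v;
                a2[c] += w * d2v; a3[c] += w * d3v;
              }
            }
          }
          float* dxc = dX.colptr(v);
          for (int c = 0; c < C; ++c) dxc[c] = a0[c];
          for (int c = 0; c < C; ++c) dxc[C + c] = a1[c];
          for (int c = 0; c < C; ++c) dxc[2 * C + c] = a2[c];
          for (int c = 0; c < C; ++c) dxc[3 * C + c] = a3[c];
        }
        for (; x < d0; ++x)
          conv_dx_voxel<C>(dY, wp, dm, km, F, x, y, z, row + x, dX);
      }
  }
}

template <int C, int FT>
VOXSR_CLONES
static void conv_bwd_dx_tpl2(const fmat& dY, const fmat& WT, Dims dm, int B,
                            const KernelMap& km, fmat& dX) {
  const int F = FT; const int K = km.K;
  const long V = dm.V();
  const int d0 = dm.d[0], p0 = (d0 > 1) ? 1 : 0;
  const float* wp = WT.memptr();
  std::vector<int> tv(K);
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y) {
        const long row = base + (long)d0 * (y + (long)dm.d[1] * z);
        int ntv = 0;
        for (int t = 0; t < K; ++t) {
          const int yy = y - km.ob[t], zz = z - km.oc[t];
          if (yy >= 0 && yy < dm.d[1] && zz >= 0 && zz < dm.d[2])
            tv[ntv++] = t;
        }
        int x = 0;
        for (; x < p0; ++x)
          conv_dx_voxel<C>(dY, wp, dm, km, F, x, y, z, row + x, dX);
        const int xin = d0 - p0;
        for (; x + 3 < xin; x += 4) {
          const long v = row + x;
          float a0[C], a1[C], a2[C], a3[C];
          for (int c = 0; c < C; ++c) a0[c] = a1[c] = a2[c] = a3[c] = 0.0f;
          for (int it = 0; it < ntv; ++it) {
            const int t = tv[it];
            const float* dyc = dY.colptr(v - km.delta[t]);
            const float* wt = wp + (size_t)t * F * C;
            for (int f = 0; f < F; ++f) {
              const float d0v = dyc[f], d1v = dyc[F + f],
                          d2v = dyc[2 * F + f], d3v = dyc[3 * F + f];
              const float* wc = wt + (size_t)f * C;
              for (int c = 0; c < C; ++c) {
                const float w = wc[c];
                a0[c] += w * d0v; a1[c] += w * d1v;
                a2[c] += w * d2v; a3[c] += w * d3v;
              }
            }
          }
          float* dxc = dX.colptr(v);
          for (int c = 0; c < C; ++c) dxc[c] = a0[c];
          for (int c = 0; c < C; ++c) dxc[C + c] = a1[c];
          for (int c = 0; c < C; ++c) dxc[2 * C + c] = a2[c];
          for (int c = 0; c < C; ++c) dxc[3 * C + c] = a3[c];
        }
        for (; x < d0; ++x)
          conv_dx_voxel<C>(dY, wp, dm, km, F, x, y, z, row + x, dX);
      }
  }
}

template <int F>
static inline void conv_dw_voxel(const fmat& X, const fmat& dY, Dims dm,
                                 const KernelMap& km, int C, int x, int y,
                                 int z, long v, float* gp) {
  const float* dyc = dY.colptr(v);
  for (int t = 0; t < km.K; ++t) {
    const int xx = x + km.oa[t];
    if (xx < 0 || xx >= dm.d[0]) continue;
    const int yy = y + km.ob[t];
    if (yy < 0 || yy >= dm.d[1]) continue;
    const int zz = z + km.oc[t];
    if (zz < 0 || zz >= dm.d[2]) continue;
    const float* xc = X.colptr(v + km.delta[t]);
    float* gt = gp + (size_t)t * C * F;
    for (int c = 0; c < C; ++c) {
      const float xv = xc[c];
      float* gc = gt + (size_t)c * F;
      for (int f = 0; f < F; ++f) gc[f] += dyc[f] * xv;
    }
  }
}

template <int F>
VOXSR_CLONES
static void conv_bwd_dw_tpl(const fmat& X, const fmat& dY, Dims dm, int B,
                            const KernelMap& km, fmat& gW) {
  const int C = X.n_rows, K = km.K;
  const long V = dm.V();
  const int d0 = dm.d[0], p0 = (d0 > 1) ? 1 : 0;
  float* gp = gW.memptr();
  std::vector<int> tv(K);
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y) {
        const long row = base + (long)d0 * (y + (long)dm.d[1] * z);
        int ntv = 0;
        for (int t = 0; t < K; ++t) {
          const int yy = y + km.ob[t], zz = z + km.oc[t];
          if (yy >= 0 && yy < dm.d[1] && zz >= 0 && zz < dm.d[2])
            tv[ntv++] = t;
        }
        int x = 0;
        for (; x < p0; ++x)
          conv_dw_voxel<F>(X, dY, dm, km, C, x, y, z, row + x, gp);
        const int xin = d0 - p0;
        for (; x + 3 < xin; x += 4) {
          const long v = row + x;
          const float* dy0 = dY.colptr(v);
          for (int it = 0; it < ntv; ++it) {
            const int t = tv[it];
            const float* xc = X.colptr(v + km.delta[t]);
            float* gt = gp + (size_t)t * C * F;
            for (int c = 0; c < C; ++c) {
              const float x0 = xc[c], x1 = xc[C + c], x2 = xc[2 * C + c],
                          x3 = xc[3 * C + c];
              float* gc = gt + (size_t)c * F;
              for (int f = 0; f < F; ++f)
                gc[f] += dy0[f] * x0 + dy0[F + f] * x1 + dy0[2 * F + f] * x2 +
                         dy0[3 * F + f] * x3;
            }
          }
        }
        for (; x < d0; ++x)
          conv_dw_voxel<F>(X, dY, dm, km, C, x, y, z, row + x, gp);
      }
  }
}

template <int F, int CT>
VOXSR_CLONES
static void conv_bwd_dw_tpl2(const fmat& X, const fmat& dY, Dims dm, int B,
                            const KernelMap& km, fmat& gW) {
  const int C = CT; const int K = km.K;
  const long V = dm.V();
  const int d0 = dm.d[0], p0 = (d0 > 1) ? 1 : 0;
  float* gp = gW.memptr();
  std::vector<int> tv(K);
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y) {
        const long row = base + (long)d0 * (y + (long)dm.d[1] * z);
        int ntv = 0;
        for (int t = 0; t < K; ++t) {
          const int yy = y + km.ob[t], zz = z + km.oc[t];
          if (yy >= 0 && yy < dm.d[1] && zz >= 0 && zz < dm.d[2])
            tv[ntv++] = t;
        }
        int x = 0;
        for (; x < p0; ++x)
          conv_dw_voxel<F>(X, dY, dm, km, C, x, y, z, row + x, gp);
        const int xin = d0 - p0;
        for (; x + 3 < xin; x += 4) {
          const long v = row + x;
          const float* dy0 = dY.colptr(v);
          for (int it = 0; it < ntv; ++it) {
            const int t = tv[it];
            const float* xc = X.colptr(v + km.delta[t]);
            float* gt = gp + (size_t)t * C * F;
            for (int c = 0; c < C; ++c) {
              const float x0 = xc[c], x1 = xc[C + c], x2 = xc[2 * C + c],
                          x3 = xc[3 * C + c];
              float* gc = gt + (size_t)c * F;
              for (int f = 0; f < F; ++f)
                gc[f] += dy0[f] * x0 + dy0[F + f] * x1 + dy0[2 * F + f] * x2 +
                         dy0[3 * F + f] * x3;
            }
          }
        }
        for (; x < d0; ++x)
          conv_dw_voxel<F>(X, dY, dm, km, C, x, y, z, row + x, gp);
      }
  }
}

// generic fallbacks (template parameter -1 means runtime width)
template <>
void conv_fwd_tpl<-1>(const fmat& X, const fmat& W, const fmat& bias,
                      Dims dm, int B, const KernelMap& km, fmat& Y) {
  const int C = X.n_rows, F = Y.n_rows, K = km.K;
  const long V = dm.V();
  const float* wp = W.memptr();
  const float* bp = bias.memptr();
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y)
        for (int x = 0; x < dm.d[0]; ++x) {
          const long v = base + x + (long)dm.d[0] * (y + (long)dm.d[1] * z);
          float* yc = Y.colptr(v);
          for (int f = 0; f < F; ++f) yc[f] = bp[f];
          for (int t = 0; t < K; ++t) {
            const int xx = x + km.oa[t];
            if (xx < 0 || xx >= dm.d[0]) continue;
            const int yy = y + km.ob[t];
            if (yy < 0 || yy >= dm.d[1]) continue;
            const int zz = z + km.oc[t];
            if (zz < 0 || zz >= dm.d[2]) continue;
            const float* xc = X.colptr(v + km.delta[t]);
            const float* wt = wp + (size_t)t * C * F;
            for (int c = 0; c < C; ++c) {
              const float xv = xc[c];
              const float* wc = wt + (size_t)c * F;
              for (int f = 0; f < F; ++f) yc[f] += wc[f] * xv;
            }
          }
        }
  }
}

template <>
void conv_bwd_dx_tpl<-1>(const fmat& dY, const fmat& WT, Dims dm, int B,
                         const KernelMap& km, fmat& dX) {
  const int F = dY.n_rows, K = km.K, C = dX.n_rows;
  const long V = dm.V();
  const float* wp = WT.memptr();
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y)
        for (int x = 0; x < dm.d[0]; ++x) {
          const long v = base + x + (long)dm.d[0] * (y + (long)dm.d[1] * z);
          float* dxc = dX.colptr(v);
          for (int c = 0; c < C; ++c) dxc[c] = 0.0f;
          for (int t = 0; t < K; ++t) {
            const int xx = x - km.oa[t];
            if (xx < 0 || xx >= dm.d[0]) continue;
            const int yy = y - km.ob[t];
            if (yy < 0 || yy >= dm.d[1]) continue;
            const int zz = z - km.oc[t];
            if (zz < 0 || zz >= dm.d[2]) continue;
            const float* dyc = dY.colptr(v - km.delta[t]);
            const float* wt = wp + (size_t)t * F * C;
            for (int f = 0; f < F; ++f) {
              const float dv = dyc[f];
              const float* wc = wt + (size_t)f * C;
              for (int c = 0; c < C; ++c) dxc[c] += wc[c] * dv;
            }
          }
        }
  }
}

template <>
void conv_bwd_dw_tpl<-1>(const fmat& X, const fmat& dY, Dims dm, int B,
                         const KernelMap& km, fmat& gW) {
  const int C = X.n_rows, F = dY.n_rows, K = km.K;
  const long V = dm.V();
  float* gp = gW.memptr();
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y)
        for (int x = 0; x < dm.d[0]; ++x) {
          const long v = base + x + (long)dm.d[0] * (y + (long)dm.d[1] * z);
          const float* dyc = dY.colptr(v);
          for (int t = 0; t < K; ++t) {
            const int xx = x + km.oa[t];
            if (xx < 0 || xx >= dm.d[0]) continue;
            const int yy = y + km.ob[t];
            if (yy < 0 || yy >= dm.d[1]) continue;
            const int zz = z + km.oc[t];
            if (zz < 0 || zz >= dm.d[2]) continue;
            const float* xc = X.colptr(v + km.delta[t]);
            float* gt = gp + (size_t)t * C * F;
            for (int c = 0; c < C; ++c) {
              const float xv = xc[c];
              float* gc = gt + (size_t)c * F;
              for (int f = 0; f < F; ++f) gc[f] += dyc[f] * xv;
            }
          }
        }
  }
}

// two-level dispatch: both contiguous widths become compile-time constants
// for the channel counts a U-Net actually uses; anything else falls back to
// the runtime-width kernels
#define VOXSR_INNER(fn2, fn1, OU, IN, ...)     \
  switch (IN) {                                \
    case 1: fn2<OU, 1>(__VA_ARGS__); break;    \
    case 2: fn2<OU, 2>(__VA_ARGS__); break;    \
    case 4: fn2<OU, 4>(__VA_ARGS__); break;    \
    case 8: fn2<OU, 8>(__VA_ARGS__); break;    \
    case 16: fn2<OU, 16>(__VA_ARGS__); break;  \
    case 32: fn2<OU, 32>(__VA_ARGS__); break;  \
    case 64: fn2<OU, 64>(__VA_ARGS__); break;  \
    case 128: fn2<OU, 128>(__VA_ARGS__); break;\
    default: fn1<OU>(__VA_ARGS__);             \
  }
#define VOXSR_DISPATCH2(fn2, fn1, OU, IN, ...)                    \
  switch (OU) {                                                   \
    case 1: VOXSR_INNER(fn2, fn1, 1, IN, __VA_ARGS__) break;      \
    case 2: VOXSR_INNER(fn2, fn1, 2, IN, __VA_ARGS__) break;      \
    case 4: VOXSR_INNER(fn2, fn1, 4, IN, __VA_ARGS__) break;      \
    case 8: VOXSR_INNER(fn2, fn1, 8, IN, __VA_ARGS__) break;      \
    case 16: VOXSR_INNER(fn2, fn1, 16, IN, __VA_ARGS__) break;    \
    case 32: VOXSR_INNER(fn2, fn1, 32, IN, __VA_ARGS__) break;    \
    case 64: VOXSR_INNER(fn2, fn1, 64, IN, __VA_ARGS__) break;    \
    case 128: VOXSR_INNER(fn2, fn1, 128, IN, __VA_ARGS__) break;  \
    default: fn1<-1>(__VA_ARGS__);                                \
  }

static void conv_fwd_direct(const fmat& X, const fmat& W, const fmat& bias,
                            Dims dm, int B, const KernelMap& km, fmat& Y) {
  const int F = Y.n_rows, C = X.n_rows;
  VOXSR_DISPATCH2(conv_fwd_tpl2, conv_fwd_tpl, F, C, X, W, bias, dm, B, km, Y)
}

static void conv_bwd_dx(const fmat& dY, const fmat& W, Dims dm, int B,
                        const KernelMap& km, fmat& dX) {
  const int F = dY.n_rows, C = dX.n_rows, K = km.K;
  // transpose weights per offset so the c axis is contiguous
  fmat WT((size_t)C, (size_t)K * F);
  for (int t = 0; t < K; ++t)
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        WT(c, (size_t)t * F + f) = W(f, (size_t)t * C + c);
  VOXSR_DISPATCH2(conv_bwd_dx_tpl2, conv_bwd_dx_tpl, C, F, dY, WT, dm, B, km,
                  dX)
}

static void conv_bwd_dw(const fmat& X, const fmat& dY, Dims dm, int B,
                        const KernelMap& km, fmat& gW) {
  const int F = dY.n_rows, C = X.n_rows;
  VOXSR_DISPATCH2(conv_bwd_dw_tpl2, conv_bwd_dw_tpl, F, C, X, dY, dm, B, km,
                  gW)
}

// ---------- layers ----------

struct Conv {
  int Cin = 0, F = 0, k[3] = {1, 1, 1};
  Param W, b;  // W: (F, K*Cin)
  fmat col;    // cached input columns (train mode)
  bool unit = false;

  void setup(int cin, int f, const int kk[3], std::mt19937_64& rng) {
    Cin = cin; F = f;
    k[0] = kk[0]; k[1] = kk[1]; k[2] = kk[2];
    unit = (k[0] == 1 && k[1] == 1 && k[2] == 1);
    int K = k[0] * k[1] * k[2];
    W.init(F, K * Cin); b.init(F, 1);
    float sd = std::sqrt(2.0f / (float)(K * Cin));
    std::normal_distribution<float> nd(0.0f, sd);
    for (arma::uword i = 0; i < W.val.n_elem; ++i) W.val(i) = nd(rng);
  }
  fmat forward(const fmat& X, Dims dm, int B, bool train) {
    fmat Y;
    if (unit) {
      Y = W.val * X;
      Y.each_col() += b.val.col(0);
    } else {
      Y.set_size(F, X.n_cols);
      KernelMap km(dm, k);
      conv_fwd_direct(X, W.val, b.val, dm, B, km, Y);
    }
    if (train) col = X; else col.reset();
    return Y;
  }
  fmat backward(const fmat& dY, Dims dm, int B) {
    b.g = arma::sum(dY, 1);
    fmat dX;
    if (unit) {
      W.g = dY * col.t();
      dX = W.val.t() * dY;
    } else {
      KernelMap km(dm, k);
      W.g.zeros();
      conv_bwd_dw(col, dY, dm, B, km, W.g);
      dX.set_size(Cin, dY.n_cols);
      conv_bwd_dx(dY, W.val, dm, B, km, dX);
    }
    col.reset();
    return dX;
  }
};

struct BatchNorm {
  Param gamma, beta;
  fvec rmean, rvar;
  float mom = 0.1f, eps = 1e-5f;
  fmat xhat;
  fvec invstd;

  void setup(int C) {
    gamma.init(C, 1); gamma.val.ones();
    beta.init(C, 1);
    rmean.zeros(C); rvar.ones(C);
  }
  fmat forward(const fmat& X, bool train) {
    if (train) {
      fvec mu = arma::mean(X, 1);
      fmat cen = X.each_col() - mu;
      fvec var = arma::mean(cen % cen, 1);
      invstd = 1.0f / arma::sqrt(var + eps);
      xhat = cen.each_col() % invstd;
      rmean = (1.0f - mom) * rmean + mom * mu;
      rvar = (1.0f - mom) * rvar + mom * var;
      fmat Y = xhat.each_col() % gamma.val.col(0);
      Y.each_col() += beta.val.col(0);
      return Y;
    }
    fvec is = 1.0f / arma::sqrt(rvar + eps);
    fmat Y = (X.each_col() - rmean).each_col() % (is % gamma.val.col(0));
    Y.each_col() += beta.val.col(0);
    return Y;
  }
  fmat backward(const fmat& dY) {
    float N = (float)dY.n_cols;
    gamma.g = arma::sum(dY % xhat, 1);
    beta.g = arma::sum(dY, 1);
    fmat dxh = dY.each_col() % gamma.val.col(0);
    fvec s1 = arma::sum(dxh, 1) / N;
    fvec s2 = arma::sum(dxh % xhat, 1) / N;
    fmat dX = dxh.each_col() - s1;
    dX -= xhat.each_col() % s2;
    dX.each_col() %= invstd;
    xhat.reset();
    return dX;
  }
};

struct ConvBlock {  // conv -> batch norm -> ReLU
  Conv conv;
  BatchNorm bn;
  fmat Y;  // post-ReLU cache
  void setup(int cin, int f, const int k[3], std::mt19937_64& rng) {
    conv.setup(cin, f, k, rng);
    bn.setup(f);
  }
  fmat forward(const fmat& X, Dims dm, int B, bool train) {
    fmat y = bn.forward(conv.forward(X, dm, B, train), train);
    y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (train) Y = y;
    return y;
  }
  fmat backward(fmat dY, Dims dm, int B) {
    dY %= arma::conv_to<fmat>::from(Y > 0.0f);
    Y.reset();
    return conv.backward(bn.backward(dY), dm, B);
  }
};

struct MaxPool {
  int p[3] = {2, 2, 2};
  arma::Mat<arma::uword> arg;
  long in_cols = 0;

  fmat forward(const fmat& X, Dims dm, int B, Dims& dmo, bool train) {
    dmo.d[0] = dm.d[0] / p[0]; dmo.d[1] = dm.d[1] / p[1]; dmo.d[2] = dm.d[2] / p[2];
    long V = dm.V(), Vo = dmo.V();
    int C = X.n_rows;
    fmat Y(C, (long)B * Vo);
    arma::Mat<arma::uword> am(C, (long)B * Vo);
    for (int b = 0; b < B; ++b) {
      long bi = (long)b * V, bo = (long)b * Vo;
      for (int z = 0; z < dmo.d[2]; ++z)
        for (int y = 0; y < dmo.d[1]; ++y)
          for (int x = 0; x < dmo.d[0]; ++x) {
            long oc = bo + x + (long)dmo.d[0] * (y + (long)dmo.d[1] * z);
            for (int c = 0; c < C; ++c) {
              float best = -1e30f; long bcol = 0;
              for (int cc = 0; cc < p[2]; ++cc)
                for (int bb = 0; bb < p[1]; ++bb)
                  for (int aa = 0; aa < p[0]; ++aa) {
                    long ic = bi + (x * p[0] + aa) +
                              (long)dm.d[0] * ((y * p[1] + bb) +
                                               (long)dm.d[1] * (z * p[2] + cc));
                    float v = X(c, ic);
                    if (v > best) { best = v; bcol = ic; }
                  }
              Y(c, oc) = best;
              am(c, oc) = (arma::uword)bcol;
            }
          }
    }
    if (train) { arg = std::move(am); in_cols = X.n_cols; }
    return Y;
  }
  fmat backward(const fmat& dY, int C) {
    fmat dX(C, in_cols, arma::fill::zeros);
    for (arma::uword j = 0; j < dY.n_cols; ++j)
      for (int c = 0; c < C; ++c) dX(c, arg(c, j)) += dY(c, j);
    arg.reset();
    return dX;
  }
};

struct ConvT {  // kernel = stride = pool; no output overlap
  int Cin = 0, F = 0, p[3] = {2, 2, 2};
  Param W, b;  // W: (F*K, Cin)
  fmat Xin;

  void setup(int cin, int f, const int pp[3], std::mt19937_64& rng) {
    Cin = cin; F = f;
    p[0] = pp[0]; p[1] = pp[1]; p[2] = pp[2];
    int K = p[0] * p[1] * p[2];
    W.init(F * K, Cin); b.init(F, 1);
    float sd = std::sqrt(2.0f / (float)Cin);
    std::normal_distribution<float> nd(0.0f, sd);
    for (arma::uword i = 0; i < W.val.n_elem; ++i) W.val(i) = nd(rng);
  }
  fmat forward(const fmat& X, Dims dm, int B, Dims& dmo, bool train) {
    dmo.d[0] = dm.d[0] * p[0]; dmo.d[1] = dm.d[1] * p[1]; dmo.d[2] = dm.d[2] * p[2];
    long V = dm.V(), Vo = dmo.V();
    int K = p[0] * p[1] * p[2];
    fmat Yall = W.val * X;  // (F*K, B*V)
    fmat Y(F, (long)B * Vo);
    for (int b = 0; b < B; ++b) {
      long bi = (long)b * V, bo = (long)b * Vo;
      for (int z = 0; z < dm.d[2]; ++z)
        for (int y = 0; y < dm.d[1]; ++y)
          for (int x = 0; x < dm.d[0]; ++x) {
            long ic = bi + x + (long)dm.d[0] * (y + (long)dm.d[1] * z);
            int t = 0;
            for (int cc = 0; cc < p[2]; ++cc)
              for (int bb = 0; bb < p[1]; ++bb)
                for (int aa = 0; aa < p[0]; ++aa, ++t) {
                  long oc = bo + (x * p[0] + aa) +
                            (long)dmo.d[0] * ((y * p[1] + bb) +
                                              (long)dmo.d[1] * (z * p[2] + cc));
                  for (int f = 0; f < F; ++f)
                    Y(f, oc) = Yall(f * K + t, ic);
                }
          }
    }
    Y.each_col() += b.val.col(0);
    if (train) Xin = X; else Xin.reset();
    return Y;
  }
  fmat backward(const fmat& dY, Dims dm_in, int B) {
    long V = dm_in.V();
    int K = p[0] * p[1] * p[2];
    Dims dmo; dmo.d[0] = dm_in.d[0] * p[0]; dmo.d[1] = dm_in.d[1] * p[1];
    dmo.d[2] = dm_in.d[2] * p[2];
    long Vo = dmo.V();
    fmat dYall(F * K, (long)B * V);
    for (int b = 0; b < B; ++b) {
      long bi = (long)b * V, bo = (long)b * Vo;
      for (int z = 0; z < dm_in.d[2]; ++z)
        for (int y = 0; y < dm_in.d[1]; ++y)
          for (int x = 0; x < dm_in.d[0]; ++x) {
            long ic = bi + x + (long)dm_in.d[0] * (y + (long)dm_in.d[1] * z);
            int t = 0;
            for (int cc = 0; cc < p[2]; ++cc)
              for (int bb = 0; bb < p[1]; ++bb)
                for (int aa = 0; aa < p[0]; ++aa, ++t) {
                  long oc = bo + (x * p[0] + aa) +
                            (long)dmo.d[0] * ((y * p[1] + bb) +
                                              (long)dmo.d[1] * (z * p[2] + cc));
                  for (int f = 0; f < F; ++f)
                    dYall(f * K + t, ic) = dY(f, oc);
                }
          }
    }
    b.g.zeros(F, 1);
    for (arma::uword j = 0; j < dY.n_cols; ++j)
      for (int f = 0; f < F; ++f) b.g(f, 0) += dY(f, j);
    W.g = dYall * Xin.t();
    fmat dX = W.val.t() * dYall;
    Xin.reset();
    return dX;
  }
};

// ---------- the network ----------

struct UNet {
  int ndim = 3, F0 = 64;
  std::vector<int> blocks;  // 9 stage block counts
  int k[3], p[3];
  std::vector<std::vector<ConvBlock>> encB{4}, decB{4};
  std::vector<Conv> encP{4}, decP{4};
  std::vector<MaxPool> pools{4};
  std::vector<ConvBlock> latB;
  std::vector<ConvT> ups{4};
  Conv head;
  int adam_t = 0;

  // caches for backward
  fmat skips[4];
  Dims skipDims[4];
  fmat decT[4];   // transposed-conv outputs (residual sources)
  fmat ysig;      // sigmoid output
  Dims dims0;
  int lastB = 0;

  int encOut(int s) const { return F0 << s; }

  void build(int nd, int f0, const std::vector<int>& bl, int ck, int pool,
             uint64_t seed) {
    ndim = nd; F0 = f0; blocks = bl;
    if (nd == 3) { k[0] = k[1] = k[2] = ck; p[0] = p[1] = p[2] = pool; }
    else { k[0] = 1; k[1] = k[2] = ck; p[0] = 1; p[1] = p[2] = pool; }
    std::mt19937_64 rng(seed);
    const int unitk[3] = {1, 1, 1};
    for (int s = 0; s < 4; ++s) {
      int cin = (s == 0) ? 1 : encOut(s - 1), cout = encOut(s);
      encB[s].resize(blocks[s]);
      for (int i = 0; i < blocks[s]; ++i)
        encB[s][i].setup(i == 0 ? cin : cout, cout, k, rng);
      encP[s].setup(cin, cout, unitk, rng);
      pools[s].p[0] = p[0]; pools[s].p[1] = p[1]; pools[s].p[2] = p[2];
    }
    int lat_in = encOut(3), lat_out = F0 << 4;
    latB.resize(blocks[4]);
    for (int i = 0; i < blocks[4]; ++i)
      latB[i].setup(i == 0 ? lat_in : lat_out, lat_out, k, rng);
    for (int s = 0; s < 4; ++s) {
      int cin = (s == 0) ? lat_out : (F0 << (4 - s));
      int G = F0 << (3 - s);
      ups[s].setup(cin, G, p, rng);
      decB[s].resize(blocks[5 + s]);
      for (int i = 0; i < blocks[5 + s]; ++i)
        decB[s][i].setup(i == 0 ? 2 * G : G, G, k, rng);
      decP[s].setup(G, G, unitk, rng);
    }
    head.setup(F0, 1, unitk, rng);
  }

  fmat forward(const fmat& X0, Dims dm, int B, bool train) {
    dims0 = dm; lastB = B;
    fmat a = X0;
    Dims cur = dm;
    for (int s = 0; s < 4; ++s) {
      fmat x0 = a;
      for (auto& blk : encB[s]) a = blk.forward(a, cur, B, train);
      a += encP[s].forward(x0, cur, B, train);
      if (train) { skips[s] = a; skipDims[s] = cur; }
      else { skips[s] = a; skipDims[s] = cur; }  // needed for concat either way
      Dims nxt;
      a = pools[s].forward(a, cur, B, nxt, train);
      cur = nxt;
    }
    for (auto& blk : latB) a = blk.forward(a, cur, B, train);
    for (int s = 0; s < 4; ++s) {
      Dims nxt;
      fmat t = ups[s].forward(a, cur, B, nxt, train);
      cur = nxt;
      fmat u = arma::join_cols(t, skips[3 - s]);
      if (train) decT[s] = t;
      a = u;
      for (auto& blk : decB[s]) a = blk.forward(a, cur, B, train);
      a += decP[s].forward(train ? decT[s] : t, cur, B, train);
      if (!train) skips[3 - s].reset();
    }
    fmat z = head.forward(a, cur, B, train);
    z.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
    if (train) ysig = z;
    return z;
  }

  void backward(const fmat& dY) {
    int B = lastB;
    fmat d = dY % ysig % (1.0f - ysig);
    ysig.reset();
    Dims cur = dims0;  // full resolution at the head
    fmat da = head.backward(d, cur, B);
    fmat dskip[4];
    for (int s = 3; s >= 0; --s) {
      // decoder stage s ran at resolution skipDims[3-s]
      Dims dcur = skipDims[3 - s];
      fmat dproj_t = decP[s].backward(da, dcur, B);
      for (int i = (int)decB[s].size() - 1; i >= 0; --i)
        da = decB[s][i].backward(da, dcur, B);
      int G = F0 << (3 - s);
      fmat dt = da.rows(0, G - 1) + dproj_t;
      dskip[3 - s] = da.rows(G, da.n_rows - 1);
      da.reset();
      Dims din;  // input resolution of the transposed conv
      din.d[0] = dcur.d[0] / p[0]; din.d[1] = dcur.d[1] / p[1];
      din.d[2] = dcur.d[2] / p[2];
      da = ups[s].backward(dt, din, B);
      decT[s].reset();
    }
    // latent at resolution skipDims[3] / pool
    Dims lat;
    lat.d[0] = skipDims[3].d[0] / p[0]; lat.d[1] = skipDims[3].d[1] / p[1];
    lat.d[2] = skipDims[3].d[2] / p[2];
    for (int i = (int)latB.size() - 1; i >= 0; --i)
      da = latB[i].backward(da, lat, B);
    for (int s = 3; s >= 0; --s) {
      Dims dcur = skipDims[s];
      int C = encOut(s);
      fmat dy = pools[s].backward(da, C);
      dy += dskip[s];
      dskip[s].reset();
      skips[s].reset();
      fmat dproj = encP[s].backward(dy, dcur, B);
      for (int i = (int)encB[s].size() - 1; i >= 0; --i)
        dy = encB[s][i].backward(dy, dcur, B);
      da = dy + dproj;
    }
  }

  template <class FN>
  void eachParam(FN fn) {
    for (int s = 0; s < 4; ++s) {
      for (size_t i = 0; i < encB[s].size(); ++i) {
        fn("enc" + std::to_string(s + 1) + ".b" + std::to_string(i + 1),
           encB[s][i]);
      }
    }
    for (size_t i = 0; i < latB.size(); ++i)
      fn("lat.b" + std::to_string(i + 1), latB[i]);
    for (int s = 0; s < 4; ++s)
      for (size_t i = 0; i < decB[s].size(); ++i)
        fn("dec" + std::to_string(s + 1) + ".b" + std::to_string(i + 1),
           decB[s][i]);
  }

  void step(float lr) {
    ++adam_t;
    auto upd = [&](ConvBlock& cb) {
      cb.conv.W.step(lr, adam_t); cb.conv.b.step(lr, adam_t);
      cb.bn.gamma.step(lr, adam_t); cb.bn.beta.step(lr, adam_t);
    };
    for (int s = 0; s < 4; ++s) {
      for (auto& cb : encB[s]) upd(cb);
      encP[s].W.step(lr, adam_t); encP[s].b.step(lr, adam_t);
    }
    for (auto& cb : latB) upd(cb);
    for (int s = 0; s < 4; ++s) {
      ups[s].W.step(lr, adam_t); ups[s].b.step(lr, adam_t);
      for (auto& cb : decB[s]) upd(cb);
      decP[s].W.step(lr, adam_t); decP[s].b.step(lr, adam_t);
    }
    head.W.step(lr, adam_t); head.b.step(lr, adam_t);
  }
};

// masked L1 + masked forward-difference gradient L1 over a batch, float;
// also fills the gradient wrt pred. Same definition as .cpp_l1grad_loss.
static double batch_loss(const fmat& pred, const fmat& target,
                         const fmat& mask, Dims dm, int B, fmat& dpred) {
  long V = dm.V();
  dpred.zeros(1, pred.n_cols);
  double s_mae = 0.0, s_g = 0.0;
  long n_mae = 0, n_g = 0;
  // first pass: counts
  for (arma::uword j = 0; j < pred.n_cols; ++j)
    if (mask(0, j) != 0.0f) ++n_mae;
  std::vector<long> strides;
  for (int b = 0; b < B; ++b) {
    long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y)
        for (int x = 0; x < dm.d[0]; ++x) {
          long c = base + x + (long)dm.d[0] * (y + (long)dm.d[1] * z);
          if (mask(0, c) == 0.0f) continue;
          long nb[3] = {-1, -1, -1};
          if (x + 1 < dm.d[0]) nb[0] = c + 1;
          if (y + 1 < dm.d[1]) nb[1] = c + dm.d[0];
          if (z + 1 < dm.d[2]) nb[2] = c + (long)dm.d[0] * dm.d[1];
          for (int t = 0; t < 3; ++t)
            if (nb[t] >= 0 && mask(0, nb[t]) != 0.0f) ++n_g;
        }
  }
  float w_mae = (n_mae > 0) ? 1.0f / (float)n_mae : 0.0f;
  float w_g = (n_g > 0) ? 1.0f / (float)n_g : 0.0f;
  for (int b = 0; b < B; ++b) {
    long base = (long)b * V;
    for (int z = 0; z < dm.d[2]; ++z)
      for (int y = 0; y < dm.d[1]; ++y)
        for (int x = 0; x < dm.d[0]; ++x) {
          long c = base + x + (long)dm.d[0] * (y + (long)dm.d[1] * z);
          if (mask(0, c) == 0.0f) continue;
          float d = pred(0, c) - target(0, c);
          s_mae += std::fabs(d);
          float sg = (d > 0.0f) ? 1.0f : (d < 0.0f ? -1.0f : 0.0f);
          dpred(0, c) += sg * w_mae;
          long nb[3] = {-1, -1, -1};
          if (x + 1 < dm.d[0]) nb[0] = c + 1;
          if (y + 1 < dm.d[1]) nb[1] = c + dm.d[0];
          if (z + 1 < dm.d[2]) nb[2] = c + (long)dm.d[0] * dm.d[1];
          for (int t = 0; t < 3; ++t) {
            if (nb[t] < 0 || mask(0, nb[t]) == 0.0f) continue;
            float g = (pred(0, nb[t]) - pred(0, c)) -
                      (target(0, nb[t]) - target(0, c));
            s_g += std::fabs(g);
            float gs = (g > 0.0f) ? 1.0f : (g < 0.0f ? -1.0f : 0.0f);
            dpred(0, nb[t]) += gs * w_g;
            dpred(0, c) -= gs * w_g;
          }
        }
  }
  double L = 0.0;
  if (n_mae > 0) L += s_mae / (double)n_mae;
  if (n_g > 0) L += s_g / (double)n_g;
  return L;
}

// ---------- R interface ----------

static fmat as_feature(const NumericVector& x, Dims& dm, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (d1, d2, d3, batch)");
  dm.d[0] = d[0]; dm.d[1] = d[1]; dm.d[2] = d[2];
  B = d[3];
  fmat X(1, x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) X(0, i) = (float)x[i];
  return X;
}

static NumericVector to_array(const fmat& Y, Dims dm, int B) {
  NumericVector out(Y.n_cols);
  for (arma::uword i = 0; i < Y.n_cols; ++i) out[i] = (double)Y(0, i);
  out.attr("dim") = IntegerVector::create(dm.d[0], dm.d[1], dm.d[2], B);
  return out;
}

static void check_divisible(const UNet& net, Dims dm) {
  int div0 = net.p[0] * net.p[0] * net.p[0] * net.p[0];
  int div = net.p[1] * net.p[1] * net.p[1] * net.p[1];
  if (dm.d[0] % div0 || dm.d[1] % div || dm.d[2] % div)
    stop("spatial dimensions must be divisible by %d (four pooling stages)",
         div);
}

// [[Rcpp::export(name = ".cpp_unet_create")]]
SEXP cpp_unet_create(int ndim, int filters, IntegerVector stage_blocks,
                     int conv_kernel, int pool, double seed) {
  if (stage_blocks.size() != 9) stop("stage_blocks must have length 9");
  std::vector<int> bl(stage_blocks.begin(), stage_blocks.end());
  XPtr<UNet> ptr(new UNet(), true);
  ptr->build(ndim, filters, bl, conv_kernel, pool, (uint64_t)seed);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_unet_predict")]]
NumericVector cpp_unet_predict(SEXP net, NumericVector x) {
  XPtr<UNet> p(net);
  Dims dm; int B;
  fmat X = as_feature(x, dm, B);
  check_divisible(*p, dm);
  fmat Y = p->forward(X, dm, B, false);
  return to_array(Y, dm, B);
}

// [[Rcpp::export(name = ".cpp_unet_train_batch")]]
double cpp_unet_train_batch(SEXP net, NumericVector x, NumericVector y,
                            NumericVector m, double lr) {
  XPtr<UNet> p(net);
  Dims dm; int B;
  fmat X = as_feature(x, dm, B);
  Dims dm2; int B2;
  fmat T = as_feature(y, dm2, B2);
  fmat M = as_feature(m, dm2, B2);
  check_divisible(*p, dm);
  fmat pred = p->forward(X, dm, B, true);
  fmat dpred;
  double L = batch_loss(pred, T, M, dm, B, dpred);
  if (!std::isfinite(L)) stop("non-finite training loss");
  p->backward(dpred);
  p->step((float)lr);
  return L;
}

// [[Rcpp::export(name = ".cpp_unet_eval_loss")]]
double cpp_unet_eval_loss(SEXP net, NumericVector x, NumericVector y,
                          NumericVector m) {
  XPtr<UNet> p(net);
  Dims dm; int B;
  fmat X = as_feature(x, dm, B);
  Dims dm2; int B2;
  fmat T = as_feature(y, dm2, B2);
  fmat M = as_feature(m, dm2, B2);
  check_divisible(*p, dm);
  fmat pred = p->forward(X, dm, B, false);
  fmat dpred;
  return batch_loss(pred, T, M, dm, B, dpred);
}

static NumericMatrix fmat_to_R(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = (double)m(i, j);
  return out;
}

static fmat R_to_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

// [[Rcpp::export(name = ".cpp_unet_get_state")]]
List cpp_unet_get_state(SEXP net) {
  XPtr<UNet> p(net);
  List out;
  auto putConv = [&](const std::string& nm, Conv& c) {
    out[nm + ".W"] = fmat_to_R(c.W.val);
    out[nm + ".bias"] = fmat_to_R(c.b.val);
  };
  p->eachParam([&](const std::string& nm, ConvBlock& cb) {
    putConv(nm + ".conv", cb.conv);
    out[nm + ".bn.gamma"] = fmat_to_R(cb.bn.gamma.val);
    out[nm + ".bn.beta"] = fmat_to_R(cb.bn.beta.val);
    out[nm + ".bn.rmean"] = fmat_to_R(fmat(cb.bn.rmean));
    out[nm + ".bn.rvar"] = fmat_to_R(fmat(cb.bn.rvar));
  });
  for (int s = 0; s < 4; ++s) {
    putConv("enc" + std::to_string(s + 1) + ".proj", p->encP[s]);
    out["up" + std::to_string(s + 1) + ".W"] = fmat_to_R(p->ups[s].W.val);
    out["up" + std::to_string(s + 1) + ".bias"] = fmat_to_R(p->ups[s].b.val);
    putConv("dec" + std::to_string(s + 1) + ".proj", p->decP[s]);
  }
  putConv("head", p->head);
  return out;
}

// [[Rcpp::export(name = ".cpp_unet_set_state")]]
void cpp_unet_set_state(SEXP net, List state) {
  XPtr<UNet> p(net);
  CharacterVector nms = state.names();
  std::map<std::string, SEXP> mp;
  for (int i = 0; i < state.size(); ++i)
    mp[as<std::string>(nms[i])] = state[i];
  auto grab = [&](const std::string& nm) -> SEXP {
    auto it = mp.find(nm);
    if (it == mp.end()) stop("checkpoint state is missing '%s'", nm.c_str());
    return it->second;
  };
  auto setP = [&](Param& prm, const std::string& nm) {
    fmat v = R_to_fmat(grab(nm));
    if (v.n_rows != prm.val.n_rows || v.n_cols != prm.val.n_cols)
      stop("incompatible network structure at '%s'", nm.c_str());
    prm.val = v;
  };
  auto setConv = [&](const std::string& nm, Conv& c) {
    setP(c.W, nm + ".W"); setP(c.b, nm + ".bias");
  };
  p->eachParam([&](const std::string& nm, ConvBlock& cb) {
    setConv(nm + ".conv", cb.conv);
    setP(cb.bn.gamma, nm + ".bn.gamma");
    setP(cb.bn.beta, nm + ".bn.beta");
    fmat rm = R_to_fmat(grab(nm + ".bn.rmean"));
    fmat rv = R_to_fmat(grab(nm + ".bn.rvar"));
    if (rm.n_rows != cb.bn.rmean.n_rows || rv.n_rows != cb.bn.rvar.n_rows)
      stop("incompatible network structure at '%s.bn'", nm.c_str());
    cb.bn.rmean = rm.col(0); cb.bn.rvar = rv.col(0);
  });
  for (int s = 0; s < 4; ++s) {
    setConv("enc" + std::to_string(s + 1) + ".proj", p->encP[s]);
    setP(p->ups[s].W, "up" + std::to_string(s + 1) + ".W");
    setP(p->ups[s].b, "up" + std::to_string(s + 1) + ".bias");
    setConv("dec" + std::to_string(s + 1) + ".proj", p->decP[s]);
  }
  setConv("head", p->head);
  p->adam_t = 0;  // fresh optimizer state after loading weights
}
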