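// Numerical kernels for the dimension-generic DenseNet and the phantom
// simulators.
//
// Feature tensors cross the R/C++ boundary laid out (voxel, channel, sample)
// in column-major order; spatial axes are flattened column-major, so voxel
// (x,y,z) of a (sx,sy,sz) grid has linear index x + sx*(y + sy*z).
//
// "Same"-size convolutions are computed as one BLAS GEMM per kernel offset
// over a zero-padded single-precision copy of the whole batch: shifting an
// image by a fixed spatial offset is a constant linear-index offset on the
// padded grid, and the zero halo absorbs every out-of-grid read.  This keeps
// all heavy arithmetic inside sgemm with no per-voxel gather/scatter.  Even
// kernels pad floor((K-1)/2) low and ceil((K-1)/2) high.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

extern "C" {
void sgemm_(const char *transa, const char *transb, const int *m,
            const int *n, const int *k, const float *alpha, const float *a,
            const int *lda, const float *b, const int *ldb, const float *beta,
            float *c, const int *ldc);
}

static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float *a, int lda, const float *b, int ldb,
                         float beta, float *c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

// Persistent grow-only scratch buffers (R is single-threaded): repeated
// layer calls would otherwise spend most of their time in page faults on
// hundreds of MB of freshly mmap'd workspace.
static std::vector<float> &workspace(int slot, size_t n) {
  static std::vector<float> ws[6];
  if (ws[slot].size() < n) ws[slot].resize(n);
  return ws[slot];
}

struct ConvGeom {
  int sx, sy, sz;       // unpadded spatial
  int kx, ky, kz;       // kernel
  int plx, ply, plz;    // low-side padding
  int Sx, Sy, Sz;       // padded spatial
  R_xlen_t V, Vp, G;    // voxel counts and guard size
  int Kd;
  ConvGeom(IntegerVector shape, IntegerVector kernel, IntegerVector pad_lo) {
    sx = shape[0]; sy = shape[1]; sz = shape[2];
    kx = kernel[0]; ky = kernel[1]; kz = kernel[2];
    plx = pad_lo[0]; ply = pad_lo[1]; plz = pad_lo[2];
    Sx = sx + kx - 1; Sy = sy + ky - 1; Sz = sz + kz - 1;
    V = static_cast<R_xlen_t>(sx) * sy * sz;
    Vp = static_cast<R_xlen_t>(Sx) * Sy * Sz;
    G = 3 * (1 + static_cast<R_xlen_t>(Sx) + static_cast<R_xlen_t>(Sx) * Sy);
    Kd = kx * ky * kz;
  }
  // linear-index offset on the padded grid for kernel offset r
  R_xlen_t offset(int r) const {
    int rx = r % kx, ry = (r / kx) % ky, rz = r / (kx * ky);
    return (rx - plx) +
           static_cast<R_xlen_t>(Sx) *
               ((ry - ply) + static_cast<R_xlen_t>(Sy) * (rz - plz));
  }
};

// Copy sample range [b0, b0+m) of a (V, C, B) double tensor into the padded
// float buffer laid out (Vp, m, C) with guards, halo and guards zeroed.
static void pad_in(const double *x, float *Xp, const ConvGeom &g, int C,
                   int Btot, int b0, int m) {
  const R_xlen_t total = 2 * g.G + g.Vp * m * C;
  std::memset(Xp, 0, total * sizeof(float));
  float *base = Xp + g.G;
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < m; ++s) {
      const double *xs = x + g.V * (c + static_cast<R_xlen_t>(C) * (b0 + s));
      float *dst0 = base + g.Vp * (s + static_cast<R_xlen_t>(m) * c);
      for (int z = 0; z < g.sz; ++z)
        for (int y = 0; y < g.sy; ++y) {
          const double *src = xs + g.sx * (y + static_cast<R_xlen_t>(g.sy) * z);
          float *dst = dst0 + (g.plx +
                               static_cast<R_xlen_t>(g.Sx) *
                                   ((y + g.ply) +
                                    static_cast<R_xlen_t>(g.Sy) * (z + g.plz)));
          for (int xx = 0; xx < g.sx; ++xx) dst[xx] = (float)src[xx];
        }
    }
}

// Extract the interior of a (Vp, m, C) padded float buffer into samples
// [b0, b0+m) of a (V, C, B) double tensor (accumulating if acc).
static void pad_out(const float *Yp, double *y, const ConvGeom &g, int C,
                    int Btot, int b0, int m) {
  const float *base = Yp + g.G;
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < m; ++s) {
      double *ys = y + g.V * (c + static_cast<R_xlen_t>(C) * (b0 + s));
      const float *src0 = base + g.Vp * (s + static_cast<R_xlen_t>(m) * c);
      for (int z = 0; z < g.sz; ++z)
        for (int y2 = 0; y2 < g.sy; ++y2) {
          double *dst = ys + g.sx * (y2 + static_cast<R_xlen_t>(g.sy) * z);
          const float *src =
              src0 + (g.plx + static_cast<R_xlen_t>(g.Sx) *
                                  ((y2 + g.ply) +
                                   static_cast<R_xlen_t>(g.Sy) * (z + g.plz)));
          for (int xx = 0; xx < g.sx; ++xx) dst[xx] = (double)src[xx];
        }
    }
}

static int conv_chunk(const ConvGeom &g, int cin, int cout, int B,
                      int nbuf_channels) {
  double per = static_cast<double>(g.Vp) * 4.0 * nbuf_channels;
  double lim = 512.0 * 1024 * 1024;
  int m = static_cast<int>(lim / std::max(per, 1.0));
  if (m < 1) m = 1;
  if (m > B) m = B;
  return m;
}

// Repack the (cin x cout) weight slice of kernel offset r into a contiguous
// float matrix (optionally transposed to cout x cin).
static void pack_w(const double *w, float *Wr, int r, int Kd, int cin,
                   int cout, bool transpose) {
  for (int o = 0; o < cout; ++o)
    for (int c = 0; c < cin; ++c) {
      float v = (float)w[r + static_cast<R_xlen_t>(Kd) * (c + static_cast<R_xlen_t>(cin) * o)];
      if (transpose) Wr[o + cout * c] = v;
      else Wr[c + cin * o] = v;
    }
}

// Convolution forward: x (V,cin,B), w (Kd,cin,cout) -> y (V,cout,B).
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           IntegerVector shape, IntegerVector kernel,
                           IntegerVector pad_lo, int cin, int cout, int B) {
  ConvGeom g(shape, kernel, pad_lo);
  NumericVector y(g.V * cout * B);
  int m0 = conv_chunk(g, cin, cout, B, cin + cout);
  std::vector<float> &Xp = workspace(0, 2 * g.G + g.Vp * m0 * cin);
  std::vector<float> &Yp = workspace(1, 2 * g.G + g.Vp * m0 * cout);
  std::vector<float> Wr(static_cast<size_t>(cin) * cout);
  for (int b0 = 0; b0 < B; b0 += m0) {
    int m = std::min(m0, B - b0);
    pad_in(REAL(x), Xp.data(), g, cin, B, b0, m);
    int M = static_cast<int>(g.Vp) * m;
    for (int r = 0; r < g.Kd; ++r) {
      pack_w(REAL(w), Wr.data(), r, g.Kd, cin, cout, false);
      sgemm('N', 'N', M, cout, cin, 1.0f, Xp.data() + g.G + g.offset(r), M,
            Wr.data(), cin, r == 0 ? 0.0f : 1.0f, Yp.data() + g.G, M);
    }
    pad_out(Yp.data(), REAL(y), g, cout, B, b0, m);
  }
  return y;
}

// Convolution backward: returns dw (Kd,cin,cout) and, if need_dx, dx.
//
// Both weight and input gradients contract the same unfolded tensor
// dYu[p, (o,r)] = dYp[p - off_r, o] (built once per chunk by Kd shifted
// copies of the padded output gradient):
//   dW[r,c,o] = sum_p Xp[p,c] dYu[p,(o,r)]   ->  Xp^T dYu, one GEMM
//   dX[q,c]   = sum_{o,r} dYu[q,(o,r)] W[r,c,o]  ->  dYu Wfold, one GEMM
// which keeps both GEMMs well-shaped even for small channel counts.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  IntegerVector shape, IntegerVector kernel,
                  IntegerVector pad_lo, int cin, int cout, int B,
                  bool need_dx) {
  ConvGeom g(shape, kernel, pad_lo);
  const int KO = g.Kd * cout;
  NumericVector dw(static_cast<R_xlen_t>(g.Kd) * cin * cout);
  NumericVector dx(need_dx ? g.V * cin * B : 0);
  int m0 = conv_chunk(g, cin, cout, B, 2 * cin + cout + KO);
  std::vector<float> &Xp = workspace(0, 2 * g.G + g.Vp * m0 * cin);
  std::vector<float> &dYp = workspace(2, 2 * g.G + g.Vp * m0 * cout);
  std::vector<float> &dYu = workspace(3, g.Vp * m0 * static_cast<size_t>(KO));
  std::vector<float> &dXp = workspace(4, need_dx ?
                                      2 * g.G + g.Vp * m0 * cin : 1);
  std::vector<float> dWm(static_cast<size_t>(cin) * KO);
  std::vector<float> Wfold;
  if (need_dx) {
    // Wfold[(o,r), c] = w[r, c, o]
    Wfold.resize(static_cast<size_t>(KO) * cin);
    for (int c = 0; c < cin; ++c)
      for (int r = 0; r < g.Kd; ++r)
        for (int o = 0; o < cout; ++o)
          Wfold[(o + cout * r) + static_cast<size_t>(KO) * c] =
              (float)REAL(w)[r + static_cast<R_xlen_t>(g.Kd) *
                                     (c + static_cast<R_xlen_t>(cin) * o)];
  }
  for (int b0 = 0; b0 < B; b0 += m0) {
    int m = std::min(m0, B - b0);
    int M = static_cast<int>(g.Vp) * m;
    pad_in(REAL(x), Xp.data(), g, cin, B, b0, m);
    pad_in(REAL(dy), dYp.data(), g, cout, B, b0, m);
    for (int r = 0; r < g.Kd; ++r) {
      R_xlen_t off = g.offset(r);
      for (int o = 0; o < cout; ++o)
        std::memcpy(dYu.data() + static_cast<size_t>(M) * (o + cout * r),
                    dYp.data() + g.G - off + static_cast<R_xlen_t>(M) * o,
                    static_cast<size_t>(M) * sizeof(float));
    }
    // dW += Xp^T dYu  (the dY halo is zero, so X halo reads contribute 0)
    sgemm('T', 'N', cin, KO, M, 1.0f, Xp.data() + g.G, M, dYu.data(), M,
          0.0f, dWm.data(), cin);
    double *dwp = REAL(dw);
    for (int o = 0; o < cout; ++o)
      for (int r = 0; r < g.Kd; ++r)
        for (int c = 0; c < cin; ++c)
          dwp[r + static_cast<R_xlen_t>(g.Kd) *
                      (c + static_cast<R_xlen_t>(cin) * o)] +=
              (double)dWm[c + static_cast<size_t>(cin) * (o + cout * r)];
    if (need_dx) {
      sgemm('N', 'N', M, cin, KO, 1.0f, dYu.data(), M, Wfold.data(), KO,
            0.0f, dXp.data() + g.G, M);
      pad_out(dXp.data(), REAL(dx), g, cin, B, b0, m);
    }
  }
  return List::create(_["dw"] = dw, _["dx"] = dx);
}

// Per-channel mean and biased variance of the first C channels of a
// (V, ctot, B) tensor (ctot >= C lets the caller pass a dense-block
// concatenation without slicing a copy).
// [[Rcpp::export]]
NumericMatrix cpp_bn_stats(NumericVector x, double V, int C, int B,
                           int ctot) {
  R_xlen_t Vn = static_cast<R_xlen_t>(V);
  NumericMatrix out(C, 2);
  const double *xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int b = 0; b < B; ++b) {
      const double *xs = xp + Vn * (c + static_cast<R_xlen_t>(ctot) * b);
      for (R_xlen_t v = 0; v < Vn; ++v) {
        s1 += xs[v];
        s2 += xs[v] * xs[v];
      }
    }
    double n = V * B;
    double mu = s1 / n;
    double var = s2 / n - mu * mu;
    out(c, 0) = mu;
    out(c, 1) = var > 0 ? var : 0.0;
  }
  return out;
}

// Fused batch-norm + ReLU forward: relu(gamma * (x - mu) * invsd + beta),
// reading the first C channels of a (V, ctot, B) tensor, writing a dense
// (V, C, B) result.
// [[Rcpp::export]]
NumericVector cpp_bn_relu_fwd(NumericVector x, double V, int C, int B,
                              NumericVector gamma, NumericVector beta,
                              NumericVector mu, NumericVector invsd,
                              int ctot) {
  R_xlen_t Vn = static_cast<R_xlen_t>(V);
  NumericVector y(Vn * C * B);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double a = gamma[c] * invsd[c];
      double d = beta[c] - mu[c] * a;
      const double *xs = xp + Vn * (c + static_cast<R_xlen_t>(ctot) * b);
      double *ys = yp + Vn * (c + static_cast<R_xlen_t>(C) * b);
      for (R_xlen_t v = 0; v < Vn; ++v) {
        double t = xs[v] * a + d;
        ys[v] = t > 0 ? t : 0.0;
      }
    }
  return y;
}

// Fused batch-norm + ReLU backward.  da is the (dense) gradient w.r.t. the
// post-ReLU activations; x is read with channel stride ctot; mu/invsd are
// the statistics used forward.  Gradients flow through the batch statistics
// (standard BN backward).  Branchless inner loops: the ReLU gate is a 0/1
// multiplier.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericVector x, NumericVector da, double V, int C,
                     int B, NumericVector gamma, NumericVector beta,
                     NumericVector mu, NumericVector invsd, int ctot) {
  R_xlen_t Vn = static_cast<R_xlen_t>(V);
  NumericVector dx(Vn * C * B);
  NumericVector dgamma(C), dbeta(C);
  const double *xp = REAL(x), *dap = REAL(da);
  double *dxp = REAL(dx);
  double n = V * B;
  for (int c = 0; c < C; ++c) {
    double a = gamma[c] * invsd[c];
    double d = beta[c] - mu[c] * a;
    double s1 = 0.0, s2 = 0.0;
    for (int b = 0; b < B; ++b) {
      const double *xs = xp + Vn * (c + static_cast<R_xlen_t>(ctot) * b);
      const double *das = dap + Vn * (c + static_cast<R_xlen_t>(C) * b);
      for (R_xlen_t v = 0; v < Vn; ++v) {
        double pre = xs[v] * a + d;
        double gate = pre > 0 ? 1.0 : 0.0;
        double g = das[v] * gate;
        s1 += g;
        s2 += g * (xs[v] - mu[c]) * invsd[c];
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    double m1 = s1 / n, m2 = s2 / n;
    for (int b = 0; b < B; ++b) {
      const double *xs = xp + Vn * (c + static_cast<R_xlen_t>(ctot) * b);
      const double *das = dap + Vn * (c + static_cast<R_xlen_t>(C) * b);
      double *dxs = dxp + Vn * (c + static_cast<R_xlen_t>(C) * b);
      for (R_xlen_t v = 0; v < Vn; ++v) {
        double pre = xs[v] * a + d;
        double gate = pre > 0 ? 1.0 : 0.0;
        double xh = (xs[v] - mu[c]) * invsd[c];
        // the ReLU gate applies to the upstream gradient only; the batch
        // mean/variance corrections reach every element
        dxs[v] = a * (das[v] * gate - m1 - xh * m2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// In-place accumulation of a dense (V, C, B) gradient into the first C
// channels of a (V, ctot, B) tensor the caller owns exclusively.
// [[Rcpp::export]]
void cpp_add_slice(NumericVector target, NumericVector src, double V, int C,
                   int B, int ctot) {
  R_xlen_t Vn = static_cast<R_xlen_t>(V);
  double *tp = REAL(target);
  const double *sp = REAL(src);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double *ts = tp + Vn * (c + static_cast<R_xlen_t>(ctot) * b);
      const double *ss = sp + Vn * (c + static_cast<R_xlen_t>(C) * b);
      for (R_xlen_t v = 0; v < Vn; ++v) ts[v] += ss[v];
    }
}

// Deterministic dropout with seed replay: element i is kept iff a
// counter-based hash of (seed, i) is >= rate, and scaled by 1/(1-rate).
// Calling with the same seed reproduces the same mask, so the backward pass
// replays it instead of caching it.
static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
NumericVector cpp_dropout_mul(NumericVector x, double rate, double seed) {
  NumericVector y(x.size());
  uint64_t s = static_cast<uint64_t>(seed);
  double scale = 1.0 / (1.0 - rate);
  uint64_t thresh =
      static_cast<uint64_t>(rate * 18446744073709551615.0);  // rate * 2^64
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint64_t h = splitmix64(s ^ (static_cast<uint64_t>(i) * 0x9e3779b97f4a7c15ULL));
    y[i] = h >= thresh ? x[i] * scale : 0.0;
  }
  return y;
}

static void pool_geom(const int *shape, int *out, int *win) {
  for (int a = 0; a < 3; ++a) {
    win[a] = shape[a] > 1 ? 2 : 1;
    out[a] = shape[a] > 1 ? shape[a] / 2 : 1;
  }
}

// Average pooling, window 2 / stride 2 per non-degenerate axis; odd trailing
// voxels are dropped (floor policy: 91 -> 45).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector shape, int C,
                              int B) {
  int sh[3] = {shape[0], shape[1], shape[2]}, os[3], win[3];
  pool_geom(sh, os, win);
  const R_xlen_t V = static_cast<R_xlen_t>(sh[0]) * sh[1] * sh[2];
  const R_xlen_t Vo = static_cast<R_xlen_t>(os[0]) * os[1] * os[2];
  const double inv = 1.0 / (win[0] * win[1] * win[2]);
  NumericVector y(Vo * C * B);
  for (R_xlen_t cb = 0; cb < static_cast<R_xlen_t>(C) * B; ++cb) {
    const double *xs = REAL(x) + V * cb;
    double *ys = REAL(y) + Vo * cb;
    for (int z = 0; z < os[2]; ++z)
      for (int yy = 0; yy < os[1]; ++yy)
        for (int xx = 0; xx < os[0]; ++xx) {
          int bx = win[0] > 1 ? 2 * xx : xx;
          int by = win[1] > 1 ? 2 * yy : yy;
          int bz = win[2] > 1 ? 2 * z : z;
          double acc = 0.0;
          for (int dz = 0; dz < win[2]; ++dz)
            for (int dy = 0; dy < win[1]; ++dy)
              for (int dxx = 0; dxx < win[0]; ++dxx)
                acc += xs[(bx + dxx) +
                          static_cast<R_xlen_t>(sh[0]) *
                              ((by + dy) + static_cast<R_xlen_t>(sh[1]) * (bz + dz))];
          ys[xx + static_cast<R_xlen_t>(os[0]) * (yy + static_cast<R_xlen_t>(os[1]) * z)] =
              acc * inv;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, IntegerVector shape, int C,
                              int B) {
  int sh[3] = {shape[0], shape[1], shape[2]}, os[3], win[3];
  pool_geom(sh, os, win);
  const R_xlen_t V = static_cast<R_xlen_t>(sh[0]) * sh[1] * sh[2];
  const R_xlen_t Vo = static_cast<R_xlen_t>(os[0]) * os[1] * os[2];
  const double inv = 1.0 / (win[0] * win[1] * win[2]);
  NumericVector dx(V * C * B);  // zero-initialised
  for (R_xlen_t cb = 0; cb < static_cast<R_xlen_t>(C) * B; ++cb) {
    double *xs = REAL(dx) + V * cb;
    const double *ys = REAL(dy) + Vo * cb;
    for (int z = 0; z < os[2]; ++z)
      for (int yy = 0; yy < os[1]; ++yy)
        for (int xx = 0; xx < os[0]; ++xx) {
          double g =
              ys[xx + static_cast<R_xlen_t>(os[0]) * (yy + static_cast<R_xlen_t>(os[1]) * z)] *
              inv;
          int bx = win[0] > 1 ? 2 * xx : xx;
          int by = win[1] > 1 ? 2 * yy : yy;
          int bz = win[2] > 1 ? 2 * z : z;
          for (int dz = 0; dz < win[2]; ++dz)
            for (int dyy = 0; dyy < win[1]; ++dyy)
              for (int dxx = 0; dxx < win[0]; ++dxx)
                xs[(bx + dxx) +
                   static_cast<R_xlen_t>(sh[0]) *
                       ((by + dyy) + static_cast<R_xlen_t>(sh[1]) * (bz + dz))] += g;
        }
  }
  return dx;
}

// Separable Gaussian smoothing with zero padding, truncated at 3.5 sigma.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector x, IntegerVector shape,
                               double sigma_vox) {
  const int sx = shape[0], sy = shape[1], sz = shape[2];
  const R_xlen_t V = static_cast<R_xlen_t>(sx) * sy * sz;
  if (sigma_vox <= 0) return clone(x);
  int rad = std::max(1, static_cast<int>(std::ceil(3.5 * sigma_vox)));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += ker[i + rad];
  }
  for (double &v : ker) v /= s;
  std::vector<double> a(REAL(x), REAL(x) + V), b(V);
  const int dims[3] = {sx, sy, sz};
  const R_xlen_t strides[3] = {1, sx, static_cast<R_xlen_t>(sx) * sy};
  for (int ax = 0; ax < 3; ++ax) {
    if (dims[ax] == 1) continue;
    const int n = dims[ax];
    const R_xlen_t st = strides[ax];
    for (int z = 0; z < (ax == 2 ? 1 : sz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : sy); ++y)
        for (int xx = 0; xx < (ax == 0 ? 1 : sx); ++xx) {
          R_xlen_t base = xx + static_cast<R_xlen_t>(sx) * (y + static_cast<R_xlen_t>(sy) * z);
          for (int i = 0; i < n; ++i) {
            double acc = 0.0;
            int lo = std::max(0, i - rad), hi = std::min(n - 1, i + rad);
            for (int j = lo; j <= hi; ++j)
              acc += a[base + st * j] * ker[j - i + rad];
            b[base + st * i] = acc;
          }
        }
    std::swap(a, b);
  }
  NumericVector out(V);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// Rigid resampling by trilinear pull-back.  The forward transform rotates by
// Rz*Ry*Rx (degrees) about the grid centre (voxel units) then translates by
// trans_vox; each output voxel samples the input at the inverse-transformed
// location, 0 outside the field of view.
// [[Rcpp::export]]
NumericVector cpp_rigid_resample(NumericVector x, IntegerVector shape,
                                 NumericVector trans_vox,
                                 NumericVector rot_deg) {
  const int sx = shape[0], sy = shape[1], sz = shape[2];
  const double d2r = M_PI / 180.0;
  const double ax = rot_deg[0] * d2r, ay = rot_deg[1] * d2r,
               az = rot_deg[2] * d2r;
  const double cx = std::cos(ax), sxr = std::sin(ax);
  const double cy = std::cos(ay), syr = std::sin(ay);
  const double cz = std::cos(az), szr = std::sin(az);
  // R = Rz Ry Rx
  double R[3][3] = {
      {cz * cy, cz * syr * sxr - szr * cx, cz * syr * cx + szr * sxr},
      {szr * cy, szr * syr * sxr + cz * cx, szr * syr * cx - cz * sxr},
      {-syr, cy * sxr, cy * cx}};
  const double ctr[3] = {(sx - 1) / 2.0, (sy - 1) / 2.0, (sz - 1) / 2.0};
  NumericVector out(static_cast<R_xlen_t>(sx) * sy * sz);
  const double *in = REAL(x);
  double *o = REAL(out);
  R_xlen_t p = 0;
  for (int z = 0; z < sz; ++z)
    for (int y = 0; y < sy; ++y)
      for (int xx = 0; xx < sx; ++xx, ++p) {
        double q[3] = {xx - ctr[0] - trans_vox[0], y - ctr[1] - trans_vox[1],
                       z - ctr[2] - trans_vox[2]};
        // src = R^T q + ctr
        double u = R[0][0] * q[0] + R[1][0] * q[1] + R[2][0] * q[2] + ctr[0];
        double v = R[0][1] * q[0] + R[1][1] * q[1] + R[2][1] * q[2] + ctr[1];
        double w = R[0][2] * q[0] + R[1][2] * q[1] + R[2][2] * q[2] + ctr[2];
        int i0 = static_cast<int>(std::floor(u));
        int j0 = static_cast<int>(std::floor(v));
        int k0 = static_cast<int>(std::floor(w));
        double fu = u - i0, fv = v - j0, fw = w - k0;
        double acc = 0.0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
              if (ii < 0 || ii >= sx || jj < 0 || jj >= sy || kk < 0 ||
                  kk >= sz)
                continue;
              double wgt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) *
                           (dk ? fw : 1 - fw);
              if (wgt > 0)
                acc += wgt * in[ii + static_cast<R_xlen_t>(sx) *
                                         (jj + static_cast<R_xlen_t>(sy) * kk)];
            }
        o[p] = acc;
      }
  return out;
}
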