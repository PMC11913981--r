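// Low-level numerical kernels: volume resampling, Euclidean distance
// transform, box-window sums (SSIM), and 3D convolution via im2col + GEMM.
// Array layout everywhere matches R column-major order: a volume of shape
// (D, H, W) has linear index d + D*h + D*H*w; a feature map (D, H, W, C)
// appends channel as the slowest dimension.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Sample a volume at arbitrary continuous 0-based index coordinates.
// M is a 4x4 affine mapping output voxel indices to input index coordinates.
// order: 0 nearest, 1 trilinear, 3 tricubic (Catmull-Rom, clamped borders).
// Coordinates within half a voxel beyond [0, n-1] count as inside (the
// border voxel's own footprint); trilinear sampling extrapolates linearly
// from the border pair there, so a resampled linear ramp stays exact.
// Coordinates further out yield cval and inside = FALSE.
// [[Rcpp::export]]
List cpp_sample_affine(NumericVector data, IntegerVector dim,
                       NumericMatrix M, IntegerVector odim,
                       int order, double cval) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const int oD = odim[0], oH = odim[1], oW = odim[2];
  const double* x = data.begin();
  NumericVector out((R_xlen_t)oD * oH * oW);
  LogicalVector inside((R_xlen_t)oD * oH * oW);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  const double eps = 1e-9;
  R_xlen_t idx = 0;
  for (int w = 0; w < oW; ++w) {
    for (int h = 0; h < oH; ++h) {
      for (int d = 0; d < oD; ++d, ++idx) {
        double cd = m00*d + m01*h + m02*w + m03;
        double ch = m10*d + m11*h + m12*w + m13;
        double cw = m20*d + m21*h + m22*w + m23;
        bool in = cd > -0.5 - eps && cd < D - 0.5 + eps &&
                  ch > -0.5 - eps && ch < H - 0.5 + eps &&
                  cw > -0.5 - eps && cw < W - 0.5 + eps;
        inside[idx] = in;
        if (!in) { out[idx] = cval; continue; }
        if (order == 0) {
          int id = clampi((int)std::lround(cd), 0, D - 1);
          int ih = clampi((int)std::lround(ch), 0, H - 1);
          int iw = clampi((int)std::lround(cw), 0, W - 1);
          out[idx] = x[id + (R_xlen_t)D * ih + (R_xlen_t)D * H * iw];
        } else if (order == 1) {
          // border pair with linear extrapolation inside the half-voxel band
          int d0 = clampi((int)std::floor(cd), 0, std::max(D - 2, 0));
          int h0 = clampi((int)std::floor(ch), 0, std::max(H - 2, 0));
          int w0 = clampi((int)std::floor(cw), 0, std::max(W - 2, 0));
          int d1 = clampi(d0 + 1, 0, D - 1);
          int h1 = clampi(h0 + 1, 0, H - 1);
          int w1 = clampi(w0 + 1, 0, W - 1);
          double td = D > 1 ? cd - d0 : 0.0;
          double th = H > 1 ? ch - h0 : 0.0;
          double tw = W > 1 ? cw - w0 : 0.0;
          double acc = 0.0;
          for (int a = 0; a < 2; ++a)
            for (int b = 0; b < 2; ++b)
              for (int c = 0; c < 2; ++c) {
                double wgt = (a ? td : 1 - td) * (b ? th : 1 - th) *
                             (c ? tw : 1 - tw);
                if (wgt == 0.0) continue;
                acc += wgt * x[(a ? d1 : d0) + (R_xlen_t)D * (b ? h1 : h0) +
                               (R_xlen_t)D * H * (c ? w1 : w0)];
              }
          out[idx] = acc;
        } else {
          int d0 = (int)std::floor(cd), h0 = (int)std::floor(ch),
              w0 = (int)std::floor(cw);
          double td = cd - d0, th = ch - h0, tw = cw - w0;
          double col[4], row[4];
          double plane[4];
          for (int c = -1; c <= 2; ++c) {
            int iw = clampi(w0 + c, 0, W - 1);
            for (int b = -1; b <= 2; ++b) {
              int ih = clampi(h0 + b, 0, H - 1);
              for (int a = -1; a <= 2; ++a) {
                int id = clampi(d0 + a, 0, D - 1);
                col[a + 1] = x[id + (R_xlen_t)D * ih + (R_xlen_t)D * H * iw];
              }
              row[b + 1] = catmull_rom(col[0], col[1], col[2], col[3], td);
            }
            plane[c + 1] = catmull_rom(row[0], row[1], row[2], row[3], th);
          }
          out[idx] = catmull_rom(plane[0], plane[1], plane[2], plane[3], tw);
        }
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Felzenszwalb & Huttenlocher 1D squared distance transform. Uses a large
// finite sentinel instead of infinity so that empty scan lines do not
// produce INF - INF = NaN in the parabola intersections.
#define EDT_BIG 1e20
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in voxels) from every voxel to the nearest TRUE voxel
// of a 3D mask. Voxels unreachable (empty mask) get Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i)
    out[i] = mask[i] ? 0.0 : EDT_BIG;
  int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax);
  // pass along D
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      R_xlen_t base = (R_xlen_t)D * h + (R_xlen_t)D * H * w;
      for (int i = 0; i < D; ++i) f[i] = out[base + i];
      dt1d(f, d, D);
      for (int i = 0; i < D; ++i) out[base + i] = d[i];
    }
  // pass along H
  for (int w = 0; w < W; ++w)
    for (int dd = 0; dd < D; ++dd) {
      R_xlen_t base = dd + (R_xlen_t)D * H * w;
      for (int i = 0; i < H; ++i) f[i] = out[base + (R_xlen_t)D * i];
      dt1d(f, d, H);
      for (int i = 0; i < H; ++i) out[base + (R_xlen_t)D * i] = d[i];
    }
  // pass along W
  for (int h = 0; h < H; ++h)
    for (int dd = 0; dd < D; ++dd) {
      R_xlen_t base = dd + (R_xlen_t)D * h;
      for (int i = 0; i < W; ++i) f[i] = out[base + (R_xlen_t)D * H * i];
      dt1d(f, d, W);
      for (int i = 0; i < W; ++i) out[base + (R_xlen_t)D * H * i] = d[i];
    }
  for (R_xlen_t i = 0; i < N; ++i)
    out[i] = out[i] >= EDT_BIG ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// Sum of x over every complete (valid) cubic window of side w.
// Output shape: dim - w + 1 per axis.
// [[Rcpp::export]]
NumericVector cpp_boxsum_valid(NumericVector x, IntegerVector dim, int w) {
  int D = dim[0], H = dim[1], W = dim[2];
  int oD = D - w + 1, oH = H - w + 1, oW = W - w + 1;
  if (oD < 1 || oH < 1 || oW < 1) stop("window larger than volume");
  // separable running sums, axis by axis
  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b((R_xlen_t)oD * H * W);
  for (int k = 0; k < W; ++k)
    for (int j = 0; j < H; ++j) {
      const double* src = a.data() + (R_xlen_t)D * j + (R_xlen_t)D * H * k;
      double* dst = b.data() + (R_xlen_t)oD * j + (R_xlen_t)oD * H * k;
      double s = 0;
      for (int i = 0; i < w; ++i) s += src[i];
      dst[0] = s;
      for (int i = 1; i < oD; ++i) { s += src[i + w - 1] - src[i - 1]; dst[i] = s; }
    }
  std::vector<double> c((R_xlen_t)oD * oH * W);
  for (int k = 0; k < W; ++k)
    for (int i = 0; i < oD; ++i) {
      const double* src = b.data() + i + (R_xlen_t)oD * H * k;
      double* dst = c.data() + i + (R_xlen_t)oD * oH * k;
      double s = 0;
      for (int j = 0; j < w; ++j) s += src[(R_xlen_t)oD * j];
      dst[0] = s;
      for (int j = 1; j < oH; ++j) {
        s += src[(R_xlen_t)oD * (j + w - 1)] - src[(R_xlen_t)oD * (j - 1)];
        dst[(R_xlen_t)oD * j] = s;
      }
    }
  NumericVector out((R_xlen_t)oD * oH * oW);
  for (int j = 0; j < oH; ++j)
    for (int i = 0; i < oD; ++i) {
      const double* src = c.data() + i + (R_xlen_t)oD * j;
      double* dst = out.begin() + i + (R_xlen_t)oD * j;
      double s = 0;
      for (int k = 0; k < w; ++k) s += src[(R_xlen_t)oD * oH * k];
      dst[0] = s;
      for (int k = 1; k < oW; ++k) {
        s += src[(R_xlen_t)oD * oH * (k + w - 1)] - src[(R_xlen_t)oD * oH * (k - 1)];
        dst[(R_xlen_t)oD * oH * k] = s;
      }
    }
  out.attr("dim") = IntegerVector::create(oD, oH, oW);
  return out;
}

// Adjoint of cpp_boxsum_valid: scatter each valid-window value g(p) back
// onto all voxels inside that window. out(q) = sum_{p : q in window(p)} g(p).
// [[Rcpp::export]]
NumericVector cpp_boxscatter(NumericVector g, IntegerVector gdim, int w,
                             IntegerVector odim) {
  int gD = gdim[0], gH = gdim[1], gW = gdim[2];
  int D = odim[0], H = odim[1], W = odim[2];
  NumericVector out((R_xlen_t)D * H * W);
  for (int pk = 0; pk < gW; ++pk)
    for (int pj = 0; pj < gH; ++pj)
      for (int pi = 0; pi < gD; ++pi) {
        double v = g[pi + (R_xlen_t)gD * pj + (R_xlen_t)gD * gH * pk];
        if (v == 0.0) continue;
        for (int k = pk; k < pk + w; ++k)
          for (int j = pj; j < pj + w; ++j) {
            double* dst = out.begin() + (R_xlen_t)D * j + (R_xlen_t)D * H * k + pi;
            for (int i = 0; i < w; ++i) dst[i] += v;
          }
      }
  out.attr("dim") = odim;
  return out;
}

// Patch matrix in transposed layout: Kt is (N x k3*C) so that, for each
// kernel offset (one column of Kt), the inner voxel loop writes a
// contiguous column. GEMMs then run as Y = Kt * Wm without a transpose.
// Convolution arithmetic runs in single precision (the customary deep
// learning precision); inputs/outputs are R doubles.
// Reusable scratch buffers: the conv working sets are tens of MB and are
// needed on every training step, so they are allocated once and recycled
// to avoid page-fault churn.
static std::vector<float>& conv_buf(int slot, size_t n) {
  static std::vector<float> bufs[4];
  if (bufs[slot].size() < n) bufs[slot].resize(n);
  return bufs[slot];
}

static void im2colT(const float* x, int D, int H, int W, int C,
                    int k, int stride, int pad,
                    int oD, int oH, int oW, arma::fmat& Kt) {
  const int k3 = k * k * k;
  std::memset(Kt.memptr(), 0, sizeof(float) * Kt.n_elem);
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (R_xlen_t)D * H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          int row = kd + k * kh + k * k * kw + k3 * c;
          float* dst = Kt.colptr(row);
          for (int ow = 0; ow < oW; ++ow) {
            int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) { dst += (R_xlen_t)oH * oD; continue; }
            const float* xw = xc + (R_xlen_t)D * H * iw;
            for (int oh = 0; oh < oH; ++oh) {
              int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) { dst += oD; continue; }
              const float* xh = xw + (R_xlen_t)D * ih;
              int id0 = -pad + kd;  // input index at od = 0
              if (stride == 1) {
                int lo = std::max(0, -id0);
                int hi = std::min(oD, D - id0);
                for (int od = lo; od < hi; ++od) dst[od] = xh[id0 + od];
                dst += oD;
              } else {
                for (int od = 0; od < oD; ++od, ++dst) {
                  int id = od * stride + id0;
                  if (id >= 0 && id < D) *dst = xh[id];
                }
              }
            }
          }
        }
  }
}

static arma::fvec to_float(const NumericVector& x, int slot) {
  std::vector<float>& b = conv_buf(slot, x.size());
  const double* src = x.begin();
  float* dst = b.data();
  for (R_xlen_t i = 0; i < x.size(); ++i) dst[i] = (float)src[i];
  return arma::fvec(b.data(), x.size(), false, true);
}

// 3D convolution, kernel k^3, same-style zero padding, given stride.
// x: (D,H,W,Cin); Wt: (k,k,k,Cin,Cout) flattened column-major; b: Cout.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dim,
                             NumericVector Wt, int k, int cin, int cout,
                             NumericVector b, int stride, int pad) {
  int D = dim[0], H = dim[1], W = dim[2];
  int oD = (D + 2 * pad - k) / stride + 1;
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  arma::uword N = (arma::uword)oD * oH * oW;
  arma::fvec xf = to_float(x, 0);
  arma::fmat Kt(conv_buf(1, N * (size_t)k * k * k * cin).data(),
                N, (arma::uword)k * k * k * cin, false, true);
  im2colT(xf.memptr(), D, H, W, cin, k, stride, pad, oD, oH, oW, Kt);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(Wt.begin(), k * k * k * cin, cout, false, true));
  arma::fmat Y(conv_buf(2, N * (size_t)cout).data(), N, cout, false, true);
  Y = Kt * Wm;  // (N, Cout)
  NumericVector out((R_xlen_t)N * cout);
  for (int c = 0; c < cout; ++c) {
    double bc = b[c];
    double* dst = out.begin() + (R_xlen_t)N * c;
    const float* src = Y.colptr(c);
    for (arma::uword i = 0; i < N; ++i) dst[i] = src[i] + bc;
  }
  out.attr("dim") = IntegerVector::create(oD, oH, oW, cout);
  return out;
}

// Backward pass of cpp_conv3d_fwd. dy: (oD,oH,oW,Cout).
// Returns dx, dW, db.
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dim,
                    NumericVector Wt, int k, int cin, int cout,
                    NumericVector dy, IntegerVector odim,
                    int stride, int pad) {
  int D = dim[0], H = dim[1], W = dim[2];
  int oD = odim[0], oH = odim[1], oW = odim[2];
  const int k3 = k * k * k;
  arma::uword N = (arma::uword)oD * oH * oW;
  arma::fvec xf = to_float(x, 0);
  arma::fmat Kt(conv_buf(1, N * (size_t)k3 * cin).data(),
                N, (arma::uword)k3 * cin, false, true);
  im2colT(xf.memptr(), D, H, W, cin, k, stride, pad, oD, oH, oW, Kt);
  arma::fvec dyf = to_float(dy, 2);
  arma::fmat dY(dyf.memptr(), N, cout, false, true);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(Wt.begin(), k3 * cin, cout, false, true));
  arma::fmat dW = Kt.t() * dY;      // (k3*Cin, Cout)
  arma::frowvec db = arma::sum(dY, 0);
  // col2im scatter-add; reads each dKt column contiguously
  arma::fmat dKt(conv_buf(3, N * (size_t)k3 * cin).data(),
                 N, (arma::uword)k3 * cin, false, true);
  dKt = dY * Wm.t();                // (N, k3*Cin)
  arma::fvec dxf((R_xlen_t)D * H * W * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    float* xc = dxf.memptr() + (R_xlen_t)D * H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          int row = kd + k * kh + k * k * kw + k3 * c;
          const float* src = dKt.colptr(row);
          for (int ow = 0; ow < oW; ++ow) {
            int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) { src += (R_xlen_t)oH * oD; continue; }
            float* xw = xc + (R_xlen_t)D * H * iw;
            for (int oh = 0; oh < oH; ++oh) {
              int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) { src += oD; continue; }
              float* xh = xw + (R_xlen_t)D * ih;
              int id0 = -pad + kd;
              if (stride == 1) {
                int lo = std::max(0, -id0);
                int hi = std::min(oD, D - id0);
                for (int od = lo; od < hi; ++od) xh[id0 + od] += src[od];
                src += oD;
              } else {
                for (int od = 0; od < oD; ++od, ++src) {
                  int id = od * stride + id0;
                  if (id >= 0 && id < D) xh[id] += *src;
                }
              }
            }
          }
        }
  }
  NumericVector dx(dxf.begin(), dxf.end());
  dx.attr("dim") = IntegerVector::create(D, H, W, cin);
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
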