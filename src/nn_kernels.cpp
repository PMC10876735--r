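// Low-level kernels for the multi-head 3D heatmap-regression network.
//
// Tensor layout: numeric arrays with dim = c(C, X, Y, Z), channel fastest.
// All convolutions use 3x3x3 kernels with zero ('same') padding; striding is
// in-plane only (1 x s x s with the z stride always 1), matching an encoder
// that halves x/y resolution per downsampling step but never the slice axis.
// Convolution is evaluated as im2col + BLAS dgemm, one z output slice at a
// time, so the column buffer stays bounded even for 256 x 256 in-plane grids.

#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>

// single-precision GEMM, resolved from the BLAS the package links against
// (declared manually: R's BLAS header only exposes the double routines)
extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc, size_t, size_t);

using namespace Rcpp;

// The convolution arithmetic runs in single precision: weights, column
// buffers and partial results are floats (converted at the R boundary),
// which halves memory traffic in the thin, bandwidth-bound GEMMs of this
// architecture.  Heatmap targets of magnitude 1e3 and Adam-scale gradients
// are far above float resolution, so the precision loss is immaterial.
static void d2f(const double* src, size_t n, std::vector<float>& dst) {
  dst.resize(n);
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

static inline int pad_before(int in, int out, int s) {
  // 'same' padding: total pad = (out-1)*s + 3 - in, excess goes after
  int p = ((out - 1) * s + 3 - in) / 2;
  return p < 0 ? 0 : p;
}

static inline int out_size(int in, int s) { return (in + s - 1) / s; }

// Gather the output slices z0..z0+nz-1 into the column buffer col
// (K x N, K = C*27, N = ox*oy*nz, column n = oxi + ox*(oyi + oy*(z-z0)),
// row r = c + C*(dx + 3*(dy + 3*dz))).  Chunking over z keeps the buffer
// bounded for large in-plane grids while still feeding BLAS one large GEMM.
static void im2col_chunk(const float* x, int C, int X, int Y, int Z,
                         int z0, int nz, int s, int ox, int oy,
                         float* col) {
  const int K = C * 27;
  const size_t N = (size_t)ox * oy * nz;
  std::memset(col, 0, sizeof(float) * K * N);
  const int padx = pad_before(X, ox, s);
  const int pady = pad_before(Y, oy, s);
  for (int zi = 0; zi < nz; ++zi) {
    const int z = z0 + zi;
    for (int dz = 0; dz < 3; ++dz) {
      const int iz = z + dz - 1;
      if (iz < 0 || iz >= Z) continue;
      for (int dy = 0; dy < 3; ++dy) {
        for (int oyi = 0; oyi < oy; ++oyi) {
          const int iy = s * oyi + dy - pady;
          if (iy < 0 || iy >= Y) continue;
          const float* xrow = x + (((size_t)iz * Y + iy) * X) * C;
          float* crow0 =
              col + ((size_t)zi * oy + oyi) * ox * K;
          for (int dx = 0; dx < 3; ++dx) {
            const int r0 = C * (dx + 3 * (dy + 3 * dz));
            const int lo = std::max(0, (padx - dx + s - 1) / s);
            const int hi = std::min(ox - 1, (X - 1 - dx + padx) / s);
            const float* src = xrow + ((size_t)(s * lo + dx - padx)) * C;
            float* dst = crow0 + (size_t)lo * K + r0;
            for (int oxi = lo; oxi <= hi; ++oxi) {
              for (int c = 0; c < C; ++c) dst[c] = src[c];
              dst += K;
              src += (size_t)s * C;
            }
          }
        }
      }
    }
  }
}

// Scatter-add the column buffer back into dx (exact adjoint of im2col_chunk).
static void col2im_chunk(const float* col, int C, int X, int Y, int Z,
                         int z0, int nz, int s, int ox, int oy,
                         float* dx) {
  const int K = C * 27;
  const int padx = pad_before(X, ox, s);
  const int pady = pad_before(Y, oy, s);
  for (int zi = 0; zi < nz; ++zi) {
    const int z = z0 + zi;
    for (int dz = 0; dz < 3; ++dz) {
      const int iz = z + dz - 1;
      if (iz < 0 || iz >= Z) continue;
      for (int dy = 0; dy < 3; ++dy) {
        for (int oyi = 0; oyi < oy; ++oyi) {
          const int iy = s * oyi + dy - pady;
          if (iy < 0 || iy >= Y) continue;
          float* xrow = dx + (((size_t)iz * Y + iy) * X) * C;
          const float* crow0 = col + ((size_t)zi * oy + oyi) * ox * K;
          for (int dx_ = 0; dx_ < 3; ++dx_) {
            const int r0 = C * (dx_ + 3 * (dy + 3 * dz));
            const int lo = std::max(0, (padx - dx_ + s - 1) / s);
            const int hi = std::min(ox - 1, (X - 1 - dx_ + padx) / s);
            float* dst = xrow + ((size_t)(s * lo + dx_ - padx)) * C;
            const float* src = crow0 + (size_t)lo * K + r0;
            for (int oxi = lo; oxi <= hi; ++oxi) {
              for (int c = 0; c < C; ++c) dst[c] += src[c];
              src += K;
              dst += (size_t)s * C;
            }
          }
        }
      }
    }
  }
}

// z chunk size keeping the column buffer around ~16 MB (small enough to
// stay cache/TLB-friendly, large enough to amortise the GEMM)
static int chunk_slices(int K, int ox, int oy, int Z) {
  const double budget = 2.0 * 1024 * 1024;   // doubles
  int nz = (int)(budget / ((double)K * ox * oy));
  if (nz < 1) nz = 1;
  if (nz > Z) nz = Z;
  return nz;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b,
                             int stride_xy, bool relu) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int cout = W.nrow();
  const int K = W.ncol();
  if (K != C * 27) stop("weight shape does not match input channels");
  const int ox = out_size(X, stride_xy), oy = out_size(Y, stride_xy);
  NumericVector y(no_init((size_t)cout * ox * oy * Z));
  const int nzc = chunk_slices(K, ox, oy, Z);
  static std::vector<float> col, xf, wf, yf;   // reused across calls
  col.resize((size_t)K * ox * oy * nzc);
  d2f(REAL(x), (size_t)C * X * Y * Z, xf);
  d2f(REAL(W), (size_t)cout * K, wf);
  yf.resize((size_t)cout * ox * oy * nzc);
  const float one = 1.0f, zero = 0.0f;
  for (int z0 = 0; z0 < Z; z0 += nzc) {
    const int nz = std::min(nzc, Z - z0);
    const int Ni = ox * oy * nz;
    im2col_chunk(xf.data(), C, X, Y, Z, z0, nz, stride_xy, ox, oy,
                 col.data());
    sgemm_("N", "N", &cout, &Ni, &K, &one, wf.data(), &cout,
           col.data(), &K, &zero, yf.data(), &cout, 1, 1);
    double* yz = REAL(y) + (size_t)z0 * cout * ox * oy;
    for (size_t n = 0; n < (size_t)Ni; ++n) {
      for (int c = 0; c < cout; ++c) {
        double v = (double)yf[n * cout + c] + b[c];
        yz[n * cout + c] = (relu && v < 0.0) ? 0.0 : v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(cout, ox, oy, Z);
  return y;
}

// dy must already be masked by the activation derivative by the caller.
// needDx = false skips the input-gradient computation (first layer).
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims,
                    NumericMatrix W, NumericVector dy, int stride_xy,
                    bool needDx = true) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int cout = W.nrow();
  const int K = W.ncol();
  const int ox = out_size(X, stride_xy), oy = out_size(Y, stride_xy);
  NumericVector dx(needDx ? (size_t)C * X * Y * Z : 0);  // zero-initialised
  NumericMatrix dW(cout, K);
  NumericVector db(cout);
  const int nzc = chunk_slices(K, ox, oy, Z);
  static std::vector<float> col, dcol, xf, wf, dyf, dwf, dxf;
  col.resize((size_t)K * ox * oy * nzc);
  dcol.resize(needDx ? (size_t)K * ox * oy * nzc : 0);
  d2f(REAL(x), (size_t)C * X * Y * Z, xf);
  d2f(REAL(W), (size_t)cout * K, wf);
  d2f(REAL(dy), (size_t)cout * ox * oy * Z, dyf);
  dwf.assign((size_t)cout * K, 0.0f);
  if (needDx) dxf.assign((size_t)C * X * Y * Z, 0.0f);
  const float one = 1.0f, zero = 0.0f;
  for (int z0 = 0; z0 < Z; z0 += nzc) {
    const int nz = std::min(nzc, Z - z0);
    const int Ni = ox * oy * nz;
    const float* dyz = dyf.data() + (size_t)z0 * cout * ox * oy;
    im2col_chunk(xf.data(), C, X, Y, Z, z0, nz, stride_xy, ox, oy,
                 col.data());
    // dW += dy_chunk %*% t(col)
    sgemm_("N", "T", &cout, &K, &Ni, &one, dyz, &cout,
           col.data(), &K, &one, dwf.data(), &cout, 1, 1);
    if (needDx) {
      // dcol = t(W) %*% dy_chunk
      sgemm_("T", "N", &K, &Ni, &cout, &one, wf.data(), &cout,
             dyz, &cout, &zero, dcol.data(), &K, 1, 1);
      col2im_chunk(dcol.data(), C, X, Y, Z, z0, nz, stride_xy, ox, oy,
                   dxf.data());
    }
    for (size_t n = 0; n < (size_t)Ni; ++n)
      for (int c = 0; c < cout; ++c) db[c] += (double)dyz[n * cout + c];
  }
  for (size_t i = 0; i < (size_t)cout * K; ++i) REAL(dW)[i] = dwf[i];
  if (needDx) {
    for (size_t i = 0; i < (size_t)C * X * Y * Z; ++i) REAL(dx)[i] = dxf[i];
    dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Insert zeros between in-plane samples: (C,X,Y,Z) -> (C,2X,2Y,Z) with
// out[c, 2i, 2j, z] = in[c, i, j, z]. A stride-1 conv on top of this
// implements the stride-(1,2,2) transpose convolution of the decoder.
// [[Rcpp::export]]
NumericVector cpp_zerostuff(NumericVector x, IntegerVector dims) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  NumericVector y((size_t)C * 2 * X * 2 * Y * Z);
  const double* xi = REAL(x);
  double* yo = REAL(y);
  for (int z = 0; z < Z; ++z)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const double* src = xi + (((size_t)z * Y + j) * X + i) * C;
        double* dst = yo + (((size_t)z * 2 * Y + 2 * j) * 2 * X + 2 * i) * C;
        std::memcpy(dst, src, C * sizeof(double));
      }
  y.attr("dim") = IntegerVector::create(C, 2 * X, 2 * Y, Z);
  return y;
}

// Adjoint of cpp_zerostuff: keep the even in-plane samples.
// [[Rcpp::export]]
NumericVector cpp_unstuff(NumericVector dy, IntegerVector dims_out) {
  const int C = dims_out[0], X2 = dims_out[1], Y2 = dims_out[2],
            Z = dims_out[3];
  const int X = X2 / 2, Y = Y2 / 2;
  NumericVector dx(no_init((size_t)C * X * Y * Z));
  const double* yi = REAL(dy);
  double* xo = REAL(dx);
  for (int z = 0; z < Z; ++z)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const double* src = yi + (((size_t)z * Y2 + 2 * j) * X2 + 2 * i) * C;
        double* dst = xo + (((size_t)z * Y + j) * X + i) * C;
        std::memcpy(dst, src, C * sizeof(double));
      }
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return dx;
}

// In-plane max pooling by integer factor f (z untouched); returns the pooled
// tensor and 1-based argmax indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dims, int f) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  if (X % f != 0 || Y % f != 0) stop("in-plane size not divisible by pool factor");
  const int ox = X / f, oy = Y / f;
  NumericVector y(no_init((size_t)C * ox * oy * Z));
  IntegerVector idx(no_init((size_t)C * ox * oy * Z));
  const double* xi = REAL(x);
  for (int z = 0; z < Z; ++z)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int wj = 0; wj < f; ++wj)
            for (int wi = 0; wi < f; ++wi) {
              const size_t p =
                  (((size_t)z * Y + (size_t)j * f + wj) * X + (size_t)i * f + wi) * C + c;
              if (xi[p] > best) { best = xi[p]; besti = p; }
            }
          const size_t o = (((size_t)z * oy + j) * ox + i) * C + c;
          y[o] = best;
          idx[o] = (int)(besti + 1);
        }
  y.attr("dim") = IntegerVector::create(C, ox, oy, Z);
  idx.attr("dim") = IntegerVector::create(C, ox, oy, Z);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Concatenate along the channel axis: (C1,X,Y,Z) + (C2,X,Y,Z).
// [[Rcpp::export]]
NumericVector cpp_concat(NumericVector a, IntegerVector da,
                         NumericVector b, IntegerVector db) {
  const int C1 = da[0], C2 = db[0], X = da[1], Y = da[2], Z = da[3];
  const size_t nvox = (size_t)X * Y * Z;
  NumericVector y(no_init((size_t)(C1 + C2) * nvox));
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  double* py = REAL(y);
  for (size_t v = 0; v < nvox; ++v) {
    std::memcpy(py + v * (C1 + C2), pa + v * C1, C1 * sizeof(double));
    std::memcpy(py + v * (C1 + C2) + C1, pb + v * C2, C2 * sizeof(double));
  }
  y.attr("dim") = IntegerVector::create(C1 + C2, X, Y, Z);
  return y;
}

// Split the gradient of a channel concatenation back into its two parts.
// [[Rcpp::export]]
List cpp_split(NumericVector dy, IntegerVector dims, int c1) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int c2 = C - c1;
  const size_t nvox = (size_t)X * Y * Z;
  NumericVector a(no_init((size_t)c1 * nvox)), b(no_init((size_t)c2 * nvox));
  const double* py = REAL(dy);
  double* pa = REAL(a);
  double* pb = REAL(b);
  for (size_t v = 0; v < nvox; ++v) {
    std::memcpy(pa + v * c1, py + v * C, c1 * sizeof(double));
    std::memcpy(pb + v * c2, py + v * C + c1, c2 * sizeof(double));
  }
  a.attr("dim") = IntegerVector::create(c1, X, Y, Z);
  b.attr("dim") = IntegerVector::create(c2, X, Y, Z);
  return List::create(_["a"] = a, _["b"] = b);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector dims_in) {
  NumericVector dx((size_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) dx[idx[k] - 1] += dy[k];
  dx.attr("dim") = dims_in;
  return dx;
}
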