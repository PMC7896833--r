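// Low-level numerical kernels: 3x3x3 convolution via im2col + BLAS gemm,
// 2x2x2 max pooling, separable Gaussian blur, trilinear ROI resampling,
// and a small FNV-1a hash used for run manifests.
//
// Tensor layout throughout: channel-fastest column-major, i.e. a tensor of
// dim (C, X, Y, Z) stores element (c, x, y, z) at c + C*(x + X*(y + Y*z)).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_extent(int n, int stride) {
  // kernel 3, pad 1
  return (n + 2 - 3) / stride + 1;
}

// Build the im2col matrix: one row per output voxel, one column per
// (input channel, kernel offset) pair, column index c + Cin*k with
// k = kx + 3*(ky + 3*kz).
// Fill a pre-zeroed (Nout x C*27) buffer with the im2col matrix.
static void im2col3d_into(double* buf, const double* x, int C, int X,
                          int Y, int Z, int stride, int Xo, int Yo,
                          int Zo) {
  const int Nout = Xo * Yo * Zo;
  // loop kernel offset outermost so writes into each column are contiguous
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int k = kx + 3 * (ky + 3 * kz);
        // valid output range along each axis for this offset
        const int ox0 = std::max(0, (1 - kx + stride - 1) / stride);
        const int oy0 = std::max(0, (1 - ky + stride - 1) / stride);
        const int oz0 = std::max(0, (1 - kz + stride - 1) / stride);
        // floor division also for negative numerators (extent-1 grids)
        const int ox1 = std::min(Xo - 1, X >= kx ? (X - kx) / stride : -1);
        const int oy1 = std::min(Yo - 1, Y >= ky ? (Y - ky) / stride : -1);
        const int oz1 = std::min(Zo - 1, Z >= kz ? (Z - kz) / stride : -1);
        for (int c = 0; c < C; ++c) {
          double* colp = buf + (size_t)Nout * (c + C * k);
          for (int oz = oz0; oz <= oz1; ++oz) {
            const int iz = oz * stride - 1 + kz;
            for (int oy = oy0; oy <= oy1; ++oy) {
              const int iy = oy * stride - 1 + ky;
              const double* src = x + c +
                (size_t)C * ((ox0 * stride - 1 + kx) + X * (iy + Y * iz));
              double* dst = colp + ox0 + Xo * (oy + Yo * oz);
              for (int ox = ox0; ox <= ox1; ++ox) {
                *dst++ = *src;
                src += (size_t)C * stride;
              }
            }
          }
        }
      }
}

static arma::mat im2col3d(const double* x, int C, int X, int Y, int Z,
                          int stride, int Xo, int Yo, int Zo) {
  arma::mat cols(Xo * Yo * Zo, C * 27, arma::fill::zeros);
  im2col3d_into(cols.memptr(), x, C, X, Y, Z, stride, Xo, Yo, Zo);
  return cols;
}

// Forward pass that also returns the im2col matrix so the backward pass
// can reuse it (identical arithmetic, no rebuild).
// [[Rcpp::export(name = ".conv3d_forward_cols")]]
List conv3d_forward_cols_cpp(NumericVector x, IntegerVector xdim,
                             NumericMatrix W, NumericVector b,
                             int stride) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = out_extent(X, stride), Yo = out_extent(Y, stride),
            Zo = out_extent(Z, stride);
  const int Cout = W.ncol();
  if (W.nrow() != C * 27) stop("weight matrix has %d rows, expected %d", W.nrow(), C * 27);
  const int Nout = Xo * Yo * Zo;
  NumericMatrix colsR(Nout, C * 27);          // zero-initialized by R
  im2col3d_into(colsR.begin(), x.begin(), C, X, Y, Z, stride, Xo, Yo, Zo);
  arma::mat cols(colsR.begin(), Nout, C * 27, false);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat O = cols * Wm;
  O.each_row() += arma::rowvec(b.begin(), Cout, false);
  NumericVector out((size_t)Cout * Nout);
  double* op = out.begin();
  for (int r = 0; r < Nout; ++r)
    for (int co = 0; co < Cout; ++co)
      op[co + (size_t)Cout * r] = O(r, co);
  out.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return List::create(_["out"] = out, _["cols"] = colsR);
}

// Backward pass reusing the cached im2col matrix.
// [[Rcpp::export(name = ".conv3d_backward_cols")]]
List conv3d_backward_cols_cpp(NumericMatrix cols, IntegerVector xdim,
                              NumericMatrix W, NumericVector dout,
                              int stride) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = out_extent(X, stride), Yo = out_extent(Y, stride),
            Zo = out_extent(Z, stride);
  const int Cout = W.ncol();
  const int Nout = Xo * Yo * Zo;
  arma::mat colsm(cols.begin(), cols.nrow(), cols.ncol(), false);
  arma::mat dO(Nout, Cout);
  const double* dp = dout.begin();
  for (int r = 0; r < Nout; ++r)
    for (int co = 0; co < Cout; ++co)
      dO(r, co) = dp[co + (size_t)Cout * r];
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dW = colsm.t() * dO;
  arma::rowvec db = arma::sum(dO, 0);
  arma::mat dcols = dO * Wm.t();

  NumericVector dx((size_t)C * X * Y * Z);
  double* dxp = dx.begin();
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int k = kx + 3 * (ky + 3 * kz);
        const int ox0 = std::max(0, (1 - kx + stride - 1) / stride);
        const int oy0 = std::max(0, (1 - ky + stride - 1) / stride);
        const int oz0 = std::max(0, (1 - kz + stride - 1) / stride);
        const int ox1 = std::min(Xo - 1, X >= kx ? (X - kx) / stride : -1);
        const int oy1 = std::min(Yo - 1, Y >= ky ? (Y - ky) / stride : -1);
        const int oz1 = std::min(Zo - 1, Z >= kz ? (Z - kz) / stride : -1);
        for (int c = 0; c < C; ++c) {
          const double* colp = dcols.colptr(c + C * k);
          for (int oz = oz0; oz <= oz1; ++oz) {
            const int iz = oz * stride - 1 + kz;
            for (int oy = oy0; oy <= oy1; ++oy) {
              const int iy = oy * stride - 1 + ky;
              double* dst = dxp + c +
                (size_t)C * ((ox0 * stride - 1 + kx) + X * (iy + Y * iz));
              const double* src = colp + ox0 + Xo * (oy + Yo * oz);
              for (int ox = ox0; ox <= ox1; ++ox) {
                *dst += *src++;
                dst += (size_t)C * stride;
              }
            }
          }
        }
      }
  dx.attr("dim") = xdim;
  NumericMatrix dWo(C * 27, Cout);
  std::copy(dW.begin(), dW.end(), dWo.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWo,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// As .conv3d_forward_cols but filling a caller-owned im2col buffer whose
// padding positions are already zero (they are never written, so a buffer
// can be reused across samples of identical shape).
// [[Rcpp::export(name = ".conv3d_forward_ws")]]
NumericVector conv3d_forward_ws_cpp(NumericVector x, IntegerVector xdim,
                                    NumericMatrix W, NumericVector b,
                                    int stride, NumericMatrix cols) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = out_extent(X, stride), Yo = out_extent(Y, stride),
            Zo = out_extent(Z, stride);
  const int Cout = W.ncol();
  const int Nout = Xo * Yo * Zo;
  if (W.nrow() != C * 27) stop("weight matrix has %d rows, expected %d", W.nrow(), C * 27);
  if (cols.nrow() != Nout || cols.ncol() != C * 27)
    stop("im2col buffer has wrong shape");
  im2col3d_into(cols.begin(), x.begin(), C, X, Y, Z, stride, Xo, Yo, Zo);
  arma::mat colsm(cols.begin(), Nout, C * 27, false);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat O = colsm * Wm;
  O.each_row() += arma::rowvec(b.begin(), Cout, false);
  NumericVector out((size_t)Cout * Nout);
  double* op = out.begin();
  for (int r = 0; r < Nout; ++r)
    for (int co = 0; co < Cout; ++co)
      op[co + (size_t)Cout * r] = O(r, co);
  out.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return out;
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericMatrix W, NumericVector b,
                                 int stride) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = out_extent(X, stride), Yo = out_extent(Y, stride),
            Zo = out_extent(Z, stride);
  const int Cout = W.ncol();
  if (W.nrow() != C * 27) stop("weight matrix has %d rows, expected %d", W.nrow(), C * 27);
  arma::mat cols = im2col3d(x.begin(), C, X, Y, Z, stride, Xo, Yo, Zo);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat O = cols * Wm;              // Nout x Cout
  O.each_row() += arma::rowvec(b.begin(), Cout, false);
  const int Nout = Xo * Yo * Zo;
  NumericVector out((size_t)Cout * Nout);
  double* op = out.begin();
  for (int r = 0; r < Nout; ++r)
    for (int co = 0; co < Cout; ++co)
      op[co + (size_t)Cout * r] = O(r, co);
  out.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericMatrix W, NumericVector dout, int stride) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = out_extent(X, stride), Yo = out_extent(Y, stride),
            Zo = out_extent(Z, stride);
  const int Cout = W.ncol();
  const int Nout = Xo * Yo * Zo;
  arma::mat cols = im2col3d(x.begin(), C, X, Y, Z, stride, Xo, Yo, Zo);
  arma::mat dO(Nout, Cout);
  const double* dp = dout.begin();
  for (int r = 0; r < Nout; ++r)
    for (int co = 0; co < Cout; ++co)
      dO(r, co) = dp[co + (size_t)Cout * r];
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dW = cols.t() * dO;                 // (C*27) x Cout
  arma::rowvec db = arma::sum(dO, 0);
  arma::mat dcols = dO * Wm.t();                // Nout x (C*27)

  NumericVector dx((size_t)C * X * Y * Z);      // zero-initialised
  double* dxp = dx.begin();
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int k = kx + 3 * (ky + 3 * kz);
        const int ox0 = std::max(0, (1 - kx + stride - 1) / stride);
        const int oy0 = std::max(0, (1 - ky + stride - 1) / stride);
        const int oz0 = std::max(0, (1 - kz + stride - 1) / stride);
        // floor division also for negative numerators (extent-1 grids)
        const int ox1 = std::min(Xo - 1, X >= kx ? (X - kx) / stride : -1);
        const int oy1 = std::min(Yo - 1, Y >= ky ? (Y - ky) / stride : -1);
        const int oz1 = std::min(Zo - 1, Z >= kz ? (Z - kz) / stride : -1);
        for (int c = 0; c < C; ++c) {
          const double* colp = dcols.colptr(c + C * k);
          for (int oz = oz0; oz <= oz1; ++oz) {
            const int iz = oz * stride - 1 + kz;
            for (int oy = oy0; oy <= oy1; ++oy) {
              const int iy = oy * stride - 1 + ky;
              double* dst = dxp + c +
                (size_t)C * ((ox0 * stride - 1 + kx) + X * (iy + Y * iz));
              const double* src = colp + ox0 + Xo * (oy + Yo * oz);
              for (int ox = ox0; ox <= ox1; ++ox) {
                *dst += *src++;
                dst += (size_t)C * stride;
              }
            }
          }
        }
      }
  dx.attr("dim") = xdim;
  NumericMatrix dWo(C * 27, Cout);
  std::copy(dW.begin(), dW.end(), dWo.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWo,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward_cpp(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  if (X % 2 || Y % 2 || Z % 2) stop("max pooling needs even spatial extents");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out((size_t)C * Xo * Yo * Zo);
  IntegerVector idx((size_t)C * Xo * Yo * Zo);
  const double* xp = x.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx) {
                const int i = c + C * ((2 * ox + kx) +
                              X * ((2 * oy + ky) + Y * (2 * oz + kz)));
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          const size_t o = c + (size_t)C * (ox + Xo * (oy + Yo * oz));
          out[o] = best;
          idx[o] = besti;
        }
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward_cpp(NumericVector dout, IntegerVector idx,
                                     IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i]] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}

static void blur_axis(std::vector<double>& v, std::vector<double>& tmp,
                      int X, int Y, int Z, int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + radius];
  }
  for (double& k : kern) k /= s;
  const int n[3] = {X, Y, Z};
  const int strd[3] = {1, X, X * Y};
  const int N = n[axis], S = strd[axis];
  tmp = v;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        int pos[3] = {x, y, z};
        const int base = x + X * (y + Y * z) - pos[axis] * S;
        double acc = 0;
        for (int i = -radius; i <= radius; ++i) {
          int p = pos[axis] + i;
          if (p < 0) p = 0;            // clamp at edges
          if (p >= N) p = N - 1;
          acc += kern[i + radius] * tmp[base + p * S];
        }
        v[x + X * (y + Y * z)] = acc;
      }
}

// [[Rcpp::export(name = ".gauss_blur3d")]]
NumericVector gauss_blur3d_cpp(NumericVector x, IntegerVector dim,
                               NumericVector sigma_vox) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  std::vector<double> v(x.begin(), x.end()), tmp;
  for (int a = 0; a < 3; ++a) blur_axis(v, tmp, X, Y, Z, a, sigma_vox[a]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear sampling of a scalar volume at arbitrary continuous voxel
// coordinates (0-based). Points outside the grid get `pad`.
// [[Rcpp::export(name = ".sample_trilinear")]]
NumericVector sample_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double pad) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const double* v = vol.begin();
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (px < 0 || py < 0 || pz < 0 || px > X - 1 || py > Y - 1 || pz > Z - 1) {
      out[i] = pad;
      continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
        z0 = (int)std::floor(pz);
    if (x0 == X - 1) x0--;
    if (y0 == Y - 1) y0--;
    if (z0 == Z - 1) z0--;
    if (X == 1) x0 = 0;
    if (Y == 1) y0 = 0;
    if (Z == 1) z0 = 0;
    const double fx = px - x0, fy = py - y0, fz = pz - z0;
    double acc = 0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          const int xi = std::min(x0 + dx, X - 1),
                    yi = std::min(y0 + dy, Y - 1),
                    zi = std::min(z0 + dz, Z - 1);
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                           (dz ? fz : 1 - fz);
          acc += w * v[xi + X * (yi + Y * zi)];
        }
    out[i] = acc;
  }
  return out;
}

// Write or accumulate a gradient segment into a caller-owned flat buffer
// (1-based offset). In-place on purpose: the buffer is a private
// accumulator of the training loop.
// [[Rcpp::export(name = ".acc_segment")]]
void acc_segment_cpp(NumericVector dest, int offset, NumericVector src,
                     bool overwrite) {
  if (offset < 1 || offset - 1 + src.size() > dest.size())
    stop("segment out of range");
  double* d = dest.begin() + (offset - 1);
  const double* s = src.begin();
  const R_xlen_t n = src.size();
  if (overwrite)
    for (R_xlen_t i = 0; i < n; ++i) d[i] = s[i];
  else
    for (R_xlen_t i = 0; i < n; ++i) d[i] += s[i];
}

// [[Rcpp::export(name = ".fnv1a_hex")]]
std::string fnv1a_hex_cpp(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof buf, "%016llx", (unsigned long long)h);
  return std::string(buf);
}
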