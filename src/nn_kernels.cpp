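// Hot loops of the volumetric network layers: 3D convolution (same padding)
// via im2col + BLAS, 2x max-pooling, and stride-2 transposed convolution.
// Tensor layout throughout: column-major R arrays [nx, ny, nz, C, N].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword off4(int nx, int ny, int nz, int c) {
  return (arma::uword)nx * ny * nz * c;
}

// im2col: rows = voxels of one example (placed at row offset row0 of a
// batch-wide matrix), cols = 27 * Cin (kernel-major: dx fastest, then dy,
// dz, then input channel).  Single precision: the convolution GEMMs run in
// float, which is ample for network training and twice the BLAS throughput.
static void im2col3(const double* x, int nx, int ny, int nz, int cin,
                    arma::fmat& col, arma::uword row0) {
  const int k = 3, pad = 1;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + off4(nx, ny, nz, c);
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          arma::uword cc = (arma::uword)c * 27 + kz * 9 + ky * 3 + kx;
          float* dst = col.colptr(cc) + row0;
          for (int z = 0; z < nz; ++z) {
            int sz = z + kz - pad;
            for (int y = 0; y < ny; ++y) {
              int sy = y + ky - pad;
              arma::uword base = (arma::uword)(z * ny + y) * nx;
              if (sz < 0 || sz >= nz || sy < 0 || sy >= ny) {
                std::fill(dst + base, dst + base + nx, 0.0f);
                continue;
              }
              const double* src = xc + ((arma::uword)(sz * ny + sy) * nx);
              int sx0 = kx - pad;
              int x0 = std::max(0, -sx0), x1 = std::min(nx, nx - sx0);
              if (x0 > 0) dst[base] = 0.0f;
              for (int xg = x0; xg < x1; ++xg)
                dst[base + xg] = (float)src[xg + sx0];
              if (x1 < nx) dst[base + nx - 1] = 0.0f;
            }
          }
        }
  }
}

// scatter a column matrix (voxels x 27*Cin) back into a gradient image
static void col2im3(const arma::fmat& col, int nx, int ny, int nz, int cin,
                    double* dx) {
  const int k = 3, pad = 1;
  for (int c = 0; c < cin; ++c) {
    double* xc = dx + off4(nx, ny, nz, c);
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          arma::uword cc = (arma::uword)c * 27 + kz * 9 + ky * 3 + kx;
          const float* src = col.colptr(cc);
          for (int z = 0; z < nz; ++z) {
            int sz = z + kz - pad;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              int sy = y + ky - pad;
              if (sy < 0 || sy >= ny) continue;
              arma::uword base = (arma::uword)(z * ny + y) * nx;
              double* dstrow = xc + ((arma::uword)(sz * ny + sy) * nx);
              int sx0 = kx - pad;
              int x0 = std::max(0, -sx0), x1 = std::min(nx, nx - sx0);
              for (int xg = x0; xg < x1; ++xg)
                dstrow[xg + sx0] += src[base + xg];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward(NumericVector x, NumericVector w,
                             NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3], n = xd[4];
  int cout = wd[4];
  if (wd[3] != cin) stop("conv3d: channel mismatch");
  arma::uword nvox = (arma::uword)nx * ny * nz;
  NumericVector y(nvox * cout * n);
  y.attr("dim") = IntegerVector::create(nx, ny, nz, cout, n);
  arma::fmat W = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), 27 * cin, cout, false, true));
  arma::fmat col(nvox * n, 27 * cin);
  for (int ex = 0; ex < n; ++ex)
    im2col3(x.begin() + nvox * cin * (arma::uword)ex, nx, ny, nz, cin, col,
            nvox * (arma::uword)ex);
  arma::fmat big = col * W;            // (nvox*n) x cout, one sgemm call
  for (int ex = 0; ex < n; ++ex) {
    double* yb = y.begin() + nvox * cout * (arma::uword)ex;
    for (int c = 0; c < cout; ++c) {
      const float* src = big.colptr(c) + nvox * (arma::uword)ex;
      double* dst = yb + nvox * (arma::uword)c;
      double b = bias[c];
      for (arma::uword v = 0; v < nvox; ++v) dst[v] = (double)src[v] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3], n = xd[4];
  int cout = wd[4];
  arma::uword nvox = (arma::uword)nx * ny * nz;
  arma::fmat W = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), 27 * cin, cout, false, true));
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::fmat col(nvox * n, 27 * cin);
  for (int ex = 0; ex < n; ++ex)
    im2col3(x.begin() + nvox * cin * (arma::uword)ex, nx, ny, nz, cin, col,
            nvox * (arma::uword)ex);
  // gather dy into the batch-row layout
  arma::fmat G(nvox * n, cout);
  arma::vec db(cout, arma::fill::zeros);
  for (int ex = 0; ex < n; ++ex) {
    const double* dyb = dy.begin() + nvox * cout * (arma::uword)ex;
    for (int c = 0; c < cout; ++c) {
      const double* src = dyb + nvox * (arma::uword)c;
      float* dst = G.colptr(c) + nvox * (arma::uword)ex;
      double acc = 0.0;
      for (arma::uword v = 0; v < nvox; ++v) {
        dst[v] = (float)src[v]; acc += src[v];
      }
      db[c] += acc;
    }
  }
  arma::fmat dW = col.t() * G;
  arma::fmat dcol = G * W.t();
  for (int ex = 0; ex < n; ++ex) {
    arma::fmat sub = dcol.rows(nvox * (arma::uword)ex,
                               nvox * (arma::uword)(ex + 1) - 1);
    col2im3(sub, nx, ny, nz, cin, dx.begin() + nvox * cin * (arma::uword)ex);
  }
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  for (arma::uword q = 0; q < dW.n_elem; ++q) dwv[q] = (double)dW(q);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool3d_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], c = xd[3], n = xd[4];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool3d: odd spatial dimension");
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  arma::uword onvox = (arma::uword)ox * oy * oz;
  NumericVector y(onvox * c * n);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, c, n);
  IntegerVector idx(y.size());
  const double* xs = x.begin();
  double* ys = y.begin();
  int* is = idx.begin();
  arma::uword inplane = (arma::uword)nx * ny;
  arma::uword per_in = (arma::uword)nx * ny * nz;
  arma::uword q = 0;
  for (arma::uword cn = 0; cn < (arma::uword)c * n; ++cn) {
    const double* xb = xs + cn * per_in;
    for (int z = 0; z < oz; ++z)
      for (int y2 = 0; y2 < oy; ++y2)
        for (int x2 = 0; x2 < ox; ++x2) {
          double best = -1e300; arma::uword bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy2 = 0; dy2 < 2; ++dy2)
              for (int dx2 = 0; dx2 < 2; ++dx2) {
                arma::uword src = (arma::uword)(2 * z + dz) * inplane +
                  (arma::uword)(2 * y2 + dy2) * nx + (2 * x2 + dx2);
                double v = xb[src];
                if (v > best) { best = v; bi = src; }
              }
          ys[q] = best;
          is[q] = (int)(cn * per_in + bi);   // 0-based into x
          ++q;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward(NumericVector dy, IntegerVector argmax,
                                 IntegerVector xdim) {
  arma::uword total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= xdim[i];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  double* d = dx.begin();
  for (int i = 0; i < dy.size(); ++i) d[argmax[i]] += dy[i];
  return dx;
}

// stride-2 transposed convolution with a 2x2x2 kernel: each input voxel
// paints a 2x2x2 output block; w dims [2,2,2,Cin,Cout]
// [[Rcpp::export]]
NumericVector convtrans3d_forward(NumericVector x, NumericVector w,
                                  NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3], n = xd[4];
  int cout = wd[4];
  int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  arma::uword invox = (arma::uword)nx * ny * nz;
  arma::uword onvox = (arma::uword)ox * oy * oz;
  NumericVector y(onvox * cout * n);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cout, n);
  // gemm formulation: out_block(voxels x 8*cout) = X(voxels x cin) * Wm
  arma::mat Wm(cin, 8 * cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int kq = 0; kq < 8; ++kq)
        Wm(ci, (arma::uword)co * 8 + kq) =
          w[(arma::uword)(co * cin + ci) * 8 + kq];
  for (int ex = 0; ex < n; ++ex) {
    arma::mat X(const_cast<double*>(x.begin()) + invox * cin * (arma::uword)ex,
                invox, cin, false, true);
    arma::mat out = X * Wm;   // voxels x (8*cout)
    double* yb = y.begin() + onvox * cout * (arma::uword)ex;
    for (int co = 0; co < cout; ++co) {
      double* yc = yb + onvox * (arma::uword)co;
      for (int z = 0; z < nz; ++z)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx) {
            arma::uword vi = (arma::uword)(z * ny + yy) * nx + xx;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy2 = 0; dy2 < 2; ++dy2)
                for (int dx2 = 0; dx2 < 2; ++dx2) {
                  int kq = dz * 4 + dy2 * 2 + dx2;
                  arma::uword oi = (arma::uword)(2 * z + dz) * ox * oy +
                    (arma::uword)(2 * yy + dy2) * ox + (2 * xx + dx2);
                  yc[oi] = out(vi, (arma::uword)co * 8 + kq) + bias[co];
                }
          }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convtrans3d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3], n = xd[4];
  int cout = wd[4];
  int ox = nx * 2, oy = ny * 2;
  arma::uword invox = (arma::uword)nx * ny * nz;
  arma::uword onvox = invox * 8;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dWm(cin, 8 * cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat Wm(cin, 8 * cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int kq = 0; kq < 8; ++kq)
        Wm(ci, (arma::uword)co * 8 + kq) =
          w[(arma::uword)(co * cin + ci) * 8 + kq];
  arma::mat G(invox, 8 * cout);
  for (int ex = 0; ex < n; ++ex) {
    const double* db_ = dy.begin() + onvox * cout * (arma::uword)ex;
    for (int co = 0; co < cout; ++co) {
      const double* gc = db_ + onvox * (arma::uword)co;
      double bsum = 0.0;
      for (int z = 0; z < nz; ++z)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx) {
            arma::uword vi = (arma::uword)(z * ny + yy) * nx + xx;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy2 = 0; dy2 < 2; ++dy2)
                for (int dx2 = 0; dx2 < 2; ++dx2) {
                  int kq = dz * 4 + dy2 * 2 + dx2;
                  arma::uword oi = (arma::uword)(2 * z + dz) * ox * oy +
                    (arma::uword)(2 * yy + dy2) * ox + (2 * xx + dx2);
                  double v = gc[oi];
                  G(vi, (arma::uword)co * 8 + kq) = v;
                  bsum += v;
                }
          }
      db[co] += bsum;
    }
    arma::mat X(const_cast<double*>(x.begin()) + invox * cin * (arma::uword)ex,
                invox, cin, false, true);
    dWm += X.t() * G;
    arma::mat dX(dx.begin() + invox * cin * (arma::uword)ex, invox, cin,
                 false, true);
    dX = G * Wm.t();
  }
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int kq = 0; kq < 8; ++kq)
        dwv[(arma::uword)(co * cin + ci) * 8 + kq] =
          dWm(ci, (arma::uword)co * 8 + kq);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
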