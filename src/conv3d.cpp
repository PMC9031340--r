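// Direct 3x3x3 same-padding 3-D convolution, forward and backward.
//
// Activations are [nvox x channels] matrices in column-major voxel order
// (x fastest), matching R's array layout. Weights are [(27 * Cin) x Cout]
// with rows ordered offset-fastest within each input-channel block; the
// offset order is dx fastest, then dy, then dz, each in -1..1.

#include <Rcpp.h>
using namespace Rcpp;

static inline void fill_offsets(int off[27][3]) {
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        off[o][0] = dx; off[o][1] = dy; off[o][2] = dz; ++o;
      }
}

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericMatrix conv3d_fwd_cpp(const NumericMatrix& X, const IntegerVector& dims,
                             const NumericMatrix& W, const NumericVector& b) {
  const int H = dims[0], Wd = dims[1], D = dims[2];
  const int nvox = H * Wd * D;
  const int Cin = X.ncol(), Cout = W.ncol();
  if (X.nrow() != nvox) stop("conv3d: input rows do not match dims");
  if (W.nrow() != 27 * Cin) stop("conv3d: weight rows do not match 27 * Cin");
  NumericMatrix Y(nvox, Cout);
  int off[27][3];
  fill_offsets(off);
  const double* xp = X.begin();
  double* yp = Y.begin();

  for (int co = 0; co < Cout; ++co) {
    double* ycol = yp + (size_t)co * nvox;
    const double bias = b[co];
    for (int v = 0; v < nvox; ++v) ycol[v] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xcol = xp + (size_t)ci * nvox;
      for (int o = 0; o < 27; ++o) {
        const double w = W(o + 27 * ci, co);
        if (w == 0.0) continue;
        const int dx = off[o][0], dy = off[o][1], dz = off[o][2];
        const int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
        const int y0 = std::max(0, -dy), y1 = std::min(Wd, Wd - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(H, H - dx);
        const int shift = dx + dy * H + dz * H * Wd;
        for (int z = z0; z < z1; ++z) {
          for (int y = y0; y < y1; ++y) {
            const int base = y * H + z * H * Wd;
            const double* __restrict__ xs = xcol + base + shift;
            double* __restrict__ yd = ycol + base;
            for (int x = x0; x < x1; ++x) yd[x] += w * xs[x];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(const NumericMatrix& X, const IntegerVector& dims,
                    const NumericMatrix& W, const NumericMatrix& dY) {
  const int H = dims[0], Wd = dims[1], D = dims[2];
  const int nvox = H * Wd * D;
  const int Cin = X.ncol(), Cout = W.ncol();
  if (dY.nrow() != nvox || dY.ncol() != Cout) stop("conv3d: bad dY shape");
  NumericMatrix dX(nvox, Cin), dW(27 * Cin, Cout);
  NumericVector db(Cout);
  int off[27][3];
  fill_offsets(off);
  const double* xp = X.begin();
  const double* dyp = dY.begin();
  double* dxp = dX.begin();

  for (int co = 0; co < Cout; ++co) {
    const double* dycol = dyp + (size_t)co * nvox;
    double acc = 0.0;
    for (int v = 0; v < nvox; ++v) acc += dycol[v];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xcol = xp + (size_t)ci * nvox;
      double* dxcol = dxp + (size_t)ci * nvox;
      for (int o = 0; o < 27; ++o) {
        const double w = W(o + 27 * ci, co);
        const int dx = off[o][0], dy = off[o][1], dz = off[o][2];
        const int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
        const int y0 = std::max(0, -dy), y1 = std::min(Wd, Wd - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(H, H - dx);
        const int shift = dx + dy * H + dz * H * Wd;
        double gw = 0.0;
        for (int z = z0; z < z1; ++z) {
          for (int y = y0; y < y1; ++y) {
            const int base = y * H + z * H * Wd;
            const double* __restrict__ xs = xcol + base + shift;
            double* __restrict__ dxs = dxcol + base + shift;
            const double* __restrict__ dyd = dycol + base;
            for (int x = x0; x < x1; ++x) gw += xs[x] * dyd[x];
            if (w != 0.0) {
              for (int x = x0; x < x1; ++x) dxs[x] += w * dyd[x];
            }
          }
        }
        dW(o + 27 * ci, co) = gw;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
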