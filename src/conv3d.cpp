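#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Same-padded 3D convolution on (n x C) feature matrices, voxels in
// (x, y, z) column-major order; weights (k^3 * Cin) x Cout with the
// kernel-offset index varying fastest (dx fastest over (-h..h)^3).
//
// Strategy: copy the input into a physically zero-padded grid; each kernel
// offset then corresponds to a constant linear shift of the padded array,
// so its contribution is one BLAS dgemm with shifted row pointers. Rows of
// the padded output that fall in the pad region accumulate garbage and are
// simply not copied out. This keeps the whole convolution at dgemm speed
// without materializing an im2col buffer.

static void padFeatures(const double* x, double* xp, int nx, int ny, int nz,
                        int C, int h) {
  const int npx = nx + 2 * h, npy = ny + 2 * h, npz = nz + 2 * h;
  const size_t n = (size_t)nx * ny * nz, np = (size_t)npx * npy * npz;
  std::fill(xp, xp + np * C, 0.0);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        std::copy(x + n * c + (size_t)nx * (y + (size_t)ny * z),
                  x + n * c + (size_t)nx * (y + (size_t)ny * z) + nx,
                  xp + np * c + h +
                    (size_t)npx * (y + h + (size_t)npy * (z + h)));
}

// [[Rcpp::export(name = ".conv3dFwdCpp")]]
NumericMatrix conv3d_fwd(NumericMatrix X, NumericMatrix W, NumericVector b,
                         IntegerVector dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.ncol(), Cout = W.ncol();
  const int h = (k - 1) / 2, k3 = k * k * k;
  const int npx = nx + 2 * h, npy = ny + 2 * h, npz = nz + 2 * h;
  const int n = nx * ny * nz, np = npx * npy * npz;
  NumericMatrix Y(n, Cout);
  std::vector<double> xpad((size_t)np * Cin), ypad((size_t)np * Cout, 0.0);
  padFeatures(REAL(X), xpad.data(), nx, ny, nz, Cin, h);
  // per-offset contiguous Cin x Cout weight slices
  std::vector<double> wj((size_t)k3 * Cin * Cout);
  const double* wp = REAL(W);
  for (int j = 0; j < k3; ++j)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        wj[(size_t)j * Cin * Cout + ci + (size_t)Cin * co] =
          wp[j + (size_t)k3 * ci + (size_t)k3 * Cin * co];
  const double one = 1.0;
  int j = 0;
  for (int dz = -h; dz <= h; ++dz)
    for (int dy = -h; dy <= h; ++dy)
      for (int dx = -h; dx <= h; ++dx, ++j) {
        const int s = dx + npx * (dy + npy * dz);
        const int r0 = s < 0 ? -s : 0;
        const int m = np - (s < 0 ? -s : s);
        if (m <= 0) continue;
        F77_CALL(dgemm)("N", "N", &m, &Cout, &Cin, &one,
                        xpad.data() + r0 + s, &np,
                        wj.data() + (size_t)j * Cin * Cout, &Cin, &one,
                        ypad.data() + r0, &np FCONE FCONE);
      }
  double* yp = REAL(Y);
  for (int co = 0; co < Cout; ++co) {
    const double bc = b[co];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double* src = ypad.data() + (size_t)np * co + h +
          (size_t)npx * (y + h + (size_t)npy * (z + h));
        double* dst = yp + (size_t)n * co + (size_t)nx * (y + (size_t)ny * z);
        for (int i = 0; i < nx; ++i) dst[i] = src[i] + bc;
      }
  }
  return Y;
}

// weight gradient: dW[(j, ci), co] = sum_i X[i + off_j, ci] * dY[i, co]
// [[Rcpp::export(name = ".conv3dDwCpp")]]
NumericMatrix conv3d_dw(NumericMatrix X, NumericMatrix dY,
                        IntegerVector dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.ncol(), Cout = dY.ncol();
  const int h = (k - 1) / 2, k3 = k * k * k;
  const int npx = nx + 2 * h, npy = ny + 2 * h, npz = nz + 2 * h;
  const int np = npx * npy * npz;
  NumericMatrix dW(k3 * Cin, Cout);
  std::vector<double> xpad((size_t)np * Cin), gpad((size_t)np * Cout);
  padFeatures(REAL(X), xpad.data(), nx, ny, nz, Cin, h);
  padFeatures(REAL(dY), gpad.data(), nx, ny, nz, Cout, h);
  std::vector<double> wjg((size_t)Cin * Cout);
  double* wp = REAL(dW);
  const double one = 1.0, zero = 0.0;
  int j = 0;
  for (int dz = -h; dz <= h; ++dz)
    for (int dy = -h; dy <= h; ++dy)
      for (int dx = -h; dx <= h; ++dx, ++j) {
        const int s = dx + npx * (dy + npy * dz);
        const int r0 = s < 0 ? -s : 0;
        const int m = np - (s < 0 ? -s : s);
        if (m <= 0) continue;
        F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m, &one,
                        xpad.data() + r0 + s, &np,
                        gpad.data() + r0, &np, &zero,
                        wjg.data(), &Cin FCONE FCONE);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            wp[j + (size_t)k3 * ci + (size_t)k3 * Cin * co] =
              wjg[ci + (size_t)Cin * co];
      }
  return dW;
}
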