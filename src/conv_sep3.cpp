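#include <Rcpp.h>
using namespace Rcpp;

// Separable zero-padded convolution of a 3D array (column-major) with odd-length
// 1D kernels along each axis. Equivalent to linear convolution with the outer
// product of the three kernels, cropped to the input extent ("same").
//
// Convolution convention: out[i] = sum_j in[i + h - j] * k[j], h = (len-1)/2,
// with out-of-range input treated as zero.

static void conv_axis0(const double* in, double* out, int nx, int ny, int nz,
                       const double* k, int kl) {
  int h = kl / 2;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const double* col = in + (size_t)nx * (y + (size_t)ny * z);
      double* oc = out + (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        int jlo = std::max(0, x + h - (nx - 1));
        int jhi = std::min(kl - 1, x + h);
        for (int j = jlo; j <= jhi; ++j) s += col[x + h - j] * k[j];
        oc[x] = s;
      }
    }
  }
}

static void conv_axis1(const double* in, double* out, int nx, int ny, int nz,
                       const double* k, int kl) {
  int h = kl / 2;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      int jlo = std::max(0, y + h - (ny - 1));
      int jhi = std::min(kl - 1, y + h);
      double* oc = out + (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) oc[x] = 0.0;
      for (int j = jlo; j <= jhi; ++j) {
        const double* ic = in + (size_t)nx * ((y + h - j) + (size_t)ny * z);
        double kv = k[j];
        for (int x = 0; x < nx; ++x) oc[x] += ic[x] * kv;
      }
    }
  }
}

static void conv_axis2(const double* in, double* out, int nx, int ny, int nz,
                       const double* k, int kl) {
  int h = kl / 2;
  for (int z = 0; z < nz; ++z) {
    int jlo = std::max(0, z + h - (nz - 1));
    int jhi = std::min(kl - 1, z + h);
    for (int y = 0; y < ny; ++y) {
      double* oc = out + (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) oc[x] = 0.0;
      for (int j = jlo; j <= jhi; ++j) {
        const double* ic = in + (size_t)nx * (y + (size_t)ny * (z + h - j));
        double kv = k[j];
        for (int x = 0; x < nx; ++x) oc[x] += ic[x] * kv;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_sep3(NumericVector arr, IntegerVector dims,
                        NumericVector kx, NumericVector ky, NumericVector kz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  if ((size_t)arr.size() != n) stop("array length does not match dims");
  if (kx.size() % 2 == 0 || ky.size() % 2 == 0 || kz.size() % 2 == 0)
    stop("kernels must have odd length");
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  conv_axis0(a.data(), b.data(), nx, ny, nz, kx.begin(), kx.size());
  conv_axis1(b.data(), a.data(), nx, ny, nz, ky.begin(), ky.size());
  conv_axis2(a.data(), b.data(), nx, ny, nz, kz.begin(), kz.size());
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}
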