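#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Separable 3D convolution with border reflection. `vol` is a numeric vector
// in column-major (x fastest) order with dims d = (nx, ny, nz); kx/ky/kz are
// odd-length kernels applied along each axis in turn.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, const NumericVector& k, int axis) {
  const int hk = (k.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const int len = n[axis];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int idx[3] = {x, y, z};
        double acc = 0.0;
        for (int t = -hk; t <= hk; ++t) {
          int p = idx[axis] + t;
          // reflect (symmetric, half-sample style collapses to full-sample
          // reflection for our kernel sizes)
          if (p < 0) p = -p;
          if (p >= len) p = 2 * len - 2 - p;
          if (p < 0) p = 0; // tiny volumes
          if (p >= len) p = len - 1;
          int q[3] = {idx[0], idx[1], idx[2]};
          q[axis] = p;
          acc += k[t + hk] * in[(size_t)q[0] + (size_t)nx * (q[1] + (size_t)ny * q[2])];
        }
        out[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_sep(NumericVector vol, IntegerVector dim,
                            NumericVector kx, NumericVector ky, NumericVector kz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  conv_axis(a, b, nx, ny, nz, kx, 0);
  conv_axis(b, a, nx, ny, nz, ky, 1);
  conv_axis(a, b, nx, ny, nz, kz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// Eigenvalues of the voxelwise symmetric 3x3 Hessian, sorted by increasing
// magnitude |l1| <= |l2| <= |l3|. Closed-form trigonometric solution.
// [[Rcpp::export]]
List cpp_hessian_eigs(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                      NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = hxx[i], b = hyy[i], c = hzz[i];
    double d = hxy[i], e = hyz[i], f = hxz[i];
    double p1 = d * d + f * f + e * e;
    double ev[3];
    if (p1 < 1e-300) {
      ev[0] = a; ev[1] = b; ev[2] = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p ; r = det(B) / 2
      double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      double b12 = d / p, b13 = f / p, b23 = e / p;
      double r = (b11 * (b22 * b33 - b23 * b23)
                - b12 * (b12 * b33 - b23 * b13)
                + b13 * (b12 * b23 - b22 * b13)) / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      ev[0] = q + 2.0 * p * std::cos(phi);                       // largest
      ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);    // smallest
      ev[1] = 3.0 * q - ev[0] - ev[2];
    }
    // sort by |.| ascending
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(ev[t]) > std::fabs(ev[t + 1])) std::swap(ev[t], ev[t + 1]);
    l1[i] = ev[0]; l2[i] = ev[1]; l3[i] = ev[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
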