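#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bilinear sample with zero padding outside the image.
static inline double bilin(const NumericMatrix &img, double py, double px) {
  const int nr = img.nrow(), nc = img.ncol();
  if (px < -1.0 || px > nc || py < -1.0 || py > nr) return 0.0;
  int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
  double fx = px - x0, fy = py - y0;
  double v = 0.0;
  for (int dy = 0; dy <= 1; ++dy) {
    int y = y0 + dy;
    if (y < 0 || y >= nr) continue;
    double wy = dy ? fy : 1.0 - fy;
    for (int dx = 0; dx <= 1; ++dx) {
      int x = x0 + dx;
      if (x < 0 || x >= nc) continue;
      double wx = dx ? fx : 1.0 - fx;
      v += wy * wx * img(y, x);
    }
  }
  return v;
}

// Parallel-beam Radon transform of a square image. Angles in radians,
// 0 = rays along grid rows, counter-clockwise positive. Rotation axis at
// the centre pixel convention ((n-1)/2, 0-based). Unit step along the ray;
// output is the line integral in pixel-length units (n_angles x n_u).
// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix img, NumericVector angles_rad) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("cpp_radon expects a square image");
  const int na = angles_rad.size();
  const double c = (n - 1) / 2.0;
  NumericMatrix out(na, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int k = 0; k < n; ++k) {
      const double u = k - c;
      double acc = 0.0;
      for (int s = 0; s < n; ++s) {
        const double sp = s - c;
        const double x = -u * st + sp * ct;
        const double y = u * ct + sp * st;
        acc += bilin(img, y + c, x + c);
      }
      out(a, k) = acc;
    }
  }
  return out;
}

// Backprojection adjoint to cpp_radon: linear interpolation along the
// detector axis, summed over angles. No angular weighting (callers scale).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filtered, NumericVector angles_rad,
                              int n_out) {
  const int na = filtered.nrow(), nu = filtered.ncol();
  if (na != angles_rad.size()) stop("angle count mismatch");
  const double c = (n_out - 1) / 2.0;
  const double cu = (nu - 1) / 2.0;
  NumericMatrix out(n_out, n_out);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int i = 0; i < n_out; ++i) {
      const double y = i - c;
      const double base = y * ct + cu;
      for (int j = 0; j < n_out; ++j) {
        const double x = j - c;
        const double t = base - x * st;
        const int t0 = (int)std::floor(t);
        if (t0 < -1 || t0 > nu - 1) continue;
        const double ft = t - t0;
        double v = 0.0;
        if (t0 >= 0) v += (1.0 - ft) * filtered(a, t0);
        if (t0 + 1 <= nu - 1) v += ft * filtered(a, t0 + 1);
        out(i, j) += v;
      }
    }
  }
  return out;
}

// k x k median filter with clamped (replicated) borders.
// [[Rcpp::export]]
NumericMatrix cpp_medfilt2(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("window must be a positive odd integer");
  const int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int m = 0;
      for (int di = -h; di <= h; ++di) {
        int y = std::min(std::max(i + di, 0), nr - 1);
        for (int dj = -h; dj <= h; ++dj) {
          int x = std::min(std::max(j + dj, 0), nc - 1);
          buf[m++] = img(y, x);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(i, j) = buf[m / 2];
    }
  }
  return out;
}

// Radial polynomial warp r' = r (1 + k1 r^2 + k2 r^4) about (xc, yc)
// (0-based pixel coordinates; x = column, y = row). invert = false renders
// the distorted frame (output pixel samples the input at the distorted
// radius); invert = true applies the fixed-point inverse mapping used for
// correction, to tolerance tol (px), max 50 iterations.
// [[Rcpp::export]]
NumericMatrix cpp_warp_radial(NumericMatrix img, double xc, double yc,
                              double k1, double k2, bool invert, double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    const double y = i - yc;
    for (int j = 0; j < nc; ++j) {
      const double x = j - xc;
      const double r = std::sqrt(x * x + y * y);
      double scale;
      if (r < 1e-12) {
        scale = 1.0;
      } else if (!invert) {
        const double r2 = r * r;
        scale = 1.0 + k1 * r2 + k2 * r2 * r2;
      } else {
        double ru = r;
        for (int it = 0; it < 50; ++it) {
          const double r2 = ru * ru;
          const double nu = r / (1.0 + k1 * r2 + k2 * r2 * r2);
          if (std::fabs(nu - ru) < tol) { ru = nu; break; }
          ru = nu;
        }
        scale = ru / r;
      }
      out(i, j) = bilin(img, yc + y * scale, xc + x * scale);
    }
  }
  return out;
}
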