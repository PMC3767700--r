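#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam projector/backprojector pair.
//
// Image convention (shared with the R side): img(i, j) holds the value at
//   x = (i - (n-1)/2) * pitch,  y = (j - (n-1)/2) * pitch   (0-based i, j),
// i.e. the first matrix index runs along +x, the second along +y, with the
// rotation axis at the grid centre. Detector bin d sits at
//   t = (d - (n_det-1)/2) * pitch.
// A projection at angle theta integrates along the direction
// (-sin(theta), cos(theta)); theta is measured counterclockwise from the
// +x detector axis, so t = x*cos(theta) + y*sin(theta).

// Exact line integrals through the piecewise-constant pixel image
// (Siddon-style): every ray is cut at the pixel-edge crossings and each
// segment contributes its exact length times the pixel value.
// Pixel edges sit at (k - n/2)*pitch, k = 0..n, so pixel (i, j) spans
// [(i - n/2), (i + 1 - n/2)) x [(j - n/2), (j + 1 - n/2)) in pixel units.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles,
                                  int n_det, double pitch) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const int na = angles.size();
  NumericMatrix sino(na, n_det);
  const double cd = (n_det - 1) / 2.0;
  const double h = n / 2.0;          // half-width in pixel units
  const double eps = 1e-12;
  std::vector<double> cross;
  cross.reserve(2 * (n + 1) + 2);

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    for (int d = 0; d < n_det; ++d) {
      const double t = d - cd;      // detector coordinate, pixel units
      // ray: x(s) = t*ct - s*st, y(s) = t*st + s*ct
      cross.clear();
      for (int k = 0; k <= n; ++k) {
        const double e = k - h;     // edge coordinate
        if (std::fabs(st) > eps) cross.push_back((t * ct - e) / st);
        if (std::fabs(ct) > eps) cross.push_back((e - t * st) / ct);
      }
      std::sort(cross.begin(), cross.end());
      double sum = 0.0;
      for (size_t m = 0; m + 1 < cross.size(); ++m) {
        const double len = cross[m + 1] - cross[m];
        if (len <= eps) continue;
        const double sm = 0.5 * (cross[m + 1] + cross[m]);
        const double x = t * ct - sm * st;
        const double y = t * st + sm * ct;
        const int i = (int)std::floor(x + h);
        const int j = (int)std::floor(y + h);
        if (i >= 0 && i < n && j >= 0 && j < n) sum += len * img(i, j);
      }
      sino(a, d) = sum * pitch;
    }
  }
  return sino;
}

// Backprojection with linear interpolation on the detector. The caller
// applies the pi/n_angles quadrature weight.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filt, NumericVector angles,
                              int n, double pitch) {
  const int na = angles.size();
  if (filt.nrow() != na) stop("filtered sinogram rows must match angles");
  const int n_det = filt.ncol();
  NumericMatrix out(n, n);
  const double c0 = (n - 1) / 2.0;
  const double cd = (n_det - 1) / 2.0;

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    for (int j = 0; j < n; ++j) {
      const double yst = (j - c0) * st + cd;
      for (int i = 0; i < n; ++i) {
        const double tf = (i - c0) * ct + yst;
        const int t0 = (int)std::floor(tf);
        const double w = tf - t0;
        double v = 0.0;
        if (t0 >= 0 && t0 < n_det) v += (1.0 - w) * filt(a, t0);
        if (t0 + 1 >= 0 && t0 + 1 < n_det) v += w * filt(a, t0 + 1);
        out(i, j) += v;
      }
    }
  }
  (void)pitch;  // geometry is handled in pixel units; kept for symmetry
  return out;
}
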