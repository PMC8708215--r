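// Parallel-beam forward projection (ray-driven, bilinear sampling) and
// pixel-driven back projection.  The physical frame is shared with the
// R-level moment code: origin at the image centre, x to the right
// (increasing array column), y upwards (decreasing array row), pixel
// spacing 1.  Detector offset of bin d (0-based) is
// (d - (n_det - 1)/2) * det_spacing, and the ray of (theta, l) is
// (x, y) = (l cos t - s sin t, l sin t + s cos t) for path parameter s.

#include <RcppArmadillo.h>

using namespace arma;

static inline double bilinear(const arma::mat& img, double row, double col) {
  const int n = img.n_rows, m = img.n_cols;
  if (row <= -1.0 || col <= -1.0 || row >= (double)n || col >= (double)m)
    return 0.0;
  int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
  double fr = row - r0, fc = col - c0;
  double v00 = 0.0, v01 = 0.0, v10 = 0.0, v11 = 0.0;
  bool r0ok = r0 >= 0 && r0 < n, r1ok = r0 + 1 >= 0 && r0 + 1 < n;
  bool c0ok = c0 >= 0 && c0 < m, c1ok = c0 + 1 >= 0 && c0 + 1 < m;
  if (r0ok && c0ok) v00 = img(r0, c0);
  if (r0ok && c1ok) v01 = img(r0, c0 + 1);
  if (r1ok && c0ok) v10 = img(r0 + 1, c0);
  if (r1ok && c1ok) v11 = img(r0 + 1, c0 + 1);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) +
         fr * ((1 - fc) * v10 + fc * v11);
}

// [[Rcpp::export]]
arma::mat radon_forward_cpp(const arma::mat& img, const arma::vec& angles,
                            int n_det, double det_spacing, double step) {
  const int n = img.n_rows;
  const int na = angles.n_elem;
  arma::mat out(n_det, na, fill::zeros);
  const double cen = (n - 1) / 2.0;
  const double dcen = (n_det - 1) / 2.0;
  // support is contained in the inscribed disk, but integrate slightly
  // beyond it so interpolation tails are not clipped
  const double tmax = n / 2.0 + 2.0;
  for (int a = 0; a < na; a++) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < n_det; d++) {
      const double l = (d - dcen) * det_spacing;
      if (std::abs(l) > n / 2.0 + 2.0) continue;  // ray misses the disk
      double acc = 0.0;
      for (double s = -tmax; s <= tmax; s += step) {
        const double x = l * ct - s * st;
        const double y = l * st + s * ct;
        acc += bilinear(img, cen - y, x + cen);
      }
      out(d, a) = acc * step;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat backproject_cpp(const arma::mat& qsino, const arma::vec& angles,
                          int n_out, double det_spacing) {
  const int n_det = qsino.n_rows;
  const int na = angles.n_elem;
  arma::mat out(n_out, n_out, fill::zeros);
  const double cen = (n_out - 1) / 2.0;
  const double dcen = (n_det - 1) / 2.0;
  arma::vec cs(na), sn(na);
  for (int a = 0; a < na; a++) {
    cs[a] = std::cos(angles[a]);
    sn[a] = std::sin(angles[a]);
  }
  for (int c = 0; c < n_out; c++) {
    const double x = c - cen;
    for (int r = 0; r < n_out; r++) {
      const double y = cen - r;
      double acc = 0.0;
      for (int a = 0; a < na; a++) {
        const double pos = (x * cs[a] + y * sn[a]) / det_spacing + dcen;
        if (pos <= -1.0 || pos >= (double)n_det) continue;
        const int p0 = (int)std::floor(pos);
        const double fp = pos - p0;
        double v0 = (p0 >= 0 && p0 < n_det) ? qsino(p0, a) : 0.0;
        double v1 = (p0 + 1 >= 0 && p0 + 1 < n_det) ? qsino(p0 + 1, a) : 0.0;
        acc += (1 - fp) * v0 + fp * v1;
      }
      out(r, c) = acc;
    }
  }
  // angles are assumed uniform over [0, pi) or [0, 2*pi); in both cases the
  // Riemann sum of the FBP integral reduces to a factor pi / n_angles
  out *= datum::pi / na;
  return out;
}
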