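#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Arc-integral rows of the pre-derivative optoacoustic system matrix.
//
// Row (d, j) holds bilinear-interpolation weights of the circle of radius
// c*t_j about detector d, scaled so that the row inner product with a
// vectorized image equals (1/r) * \int_{|x - x_d| = r} u dl, discretized by
// uniform angular quadrature on the lattice theta_i = 2*pi*i/n_theta. One
// n_theta is used for every radius (chosen by the caller from the largest
// radius) so that quadrature nodes move smoothly with r -- otherwise the
// lattice phase jumps between adjacent time samples and the subsequent
// time derivative amplifies the jitter. The matrix-free R oracle uses the
// identical lattice; the two must agree to rounding error.
//
// Coordinates: pixel (row iy, col ix) center at (ox + ix*ps, oy + iy*ps),
// 0-based; image values column-vectorized with y fastest.
// [[Rcpp::export]]
List cpp_arc_matrix(int nx, int ny, double ox, double oy, double ps,
                    NumericVector det_x, NumericVector det_y,
                    NumericVector radii, double n_theta_in) {
  const int nd = det_x.size(), nt = radii.size();
  const int npix = nx * ny;
  const double x_max = ox + (nx - 1) * ps, y_max = oy + (ny - 1) * ps;
  // bounding circle of the pixel-center rectangle (for angular windowing)
  const double gcx = 0.5 * (ox + x_max), gcy = 0.5 * (oy + y_max);
  const double gr = std::sqrt(std::pow(x_max - gcx, 2) + std::pow(y_max - gcy, 2)) + 1e-12;

  std::vector<int> out_i, out_j;
  std::vector<double> out_v;
  std::vector<double> acc(npix, 0.0);
  std::vector<int> touched;
  touched.reserve(4096);

  for (int d = 0; d < nd; ++d) {
    const double dx0 = det_x[d], dy0 = det_y[d];
    const double D = std::sqrt(std::pow(gcx - dx0, 2) + std::pow(gcy - dy0, 2));
    const double beta = std::atan2(gcy - dy0, gcx - dx0);
    for (int j = 0; j < nt; ++j) {
      const double r = radii[j];
      if (r <= 0.0) continue;
      if (D - r > gr || r - D > gr) continue;  // circle misses the grid
      const long n_theta = (long)n_theta_in;
      const double dth = 2.0 * M_PI / n_theta;
      const double w = 2.0 * M_PI / n_theta;  // dl / r
      // angular window about beta where the circle is within gr of gcenter
      long i_lo = 0, i_hi = n_theta - 1;
      double ca = (r * r + D * D - gr * gr) / (2.0 * r * D);
      if (D > 0 && ca > -1.0 && ca < 1.0) {
        const double half = std::acos(ca);
        i_lo = (long)std::floor((beta - half) / dth) - 2;
        i_hi = (long)std::ceil((beta + half) / dth) + 2;
        if (i_hi - i_lo + 1 >= n_theta) { i_lo = 0; i_hi = n_theta - 1; }
      }
      touched.clear();
      for (long i = i_lo; i <= i_hi; ++i) {
        // wrap onto the global lattice index so theta values match the oracle
        long iw = i % n_theta; if (iw < 0) iw += n_theta;
        const double th = dth * iw;
        const double px = dx0 + r * std::cos(th), py = dy0 + r * std::sin(th);
        const double gx = (px - ox) / ps, gy = (py - oy) / ps;
        if (gx < 0.0 || gx > nx - 1 || gy < 0.0 || gy > ny - 1) continue;
        int ix = (int)std::floor(gx); if (ix > nx - 2) ix = nx - 2;
        int iy = (int)std::floor(gy); if (iy > ny - 2) iy = ny - 2;
        const double fx = gx - ix, fy = gy - iy;
        const int base = ix * ny + iy;  // column-major, y fastest
        const double w00 = w * (1 - fx) * (1 - fy), w01 = w * (1 - fx) * fy;
        const double w10 = w * fx * (1 - fy), w11 = w * fx * fy;
        if (acc[base] == 0 && w00 != 0) touched.push_back(base);
        acc[base] += w00;
        if (acc[base + 1] == 0 && w01 != 0) touched.push_back(base + 1);
        acc[base + 1] += w01;
        if (acc[base + ny] == 0 && w10 != 0) touched.push_back(base + ny);
        acc[base + ny] += w10;
        if (acc[base + ny + 1] == 0 && w11 != 0) touched.push_back(base + ny + 1);
        acc[base + ny + 1] += w11;
      }
      const int row = d * nt + j;
      for (size_t k = 0; k < touched.size(); ++k) {
        const int col = touched[k];
        if (acc[col] != 0.0) {
          out_i.push_back(row);
          out_j.push_back(col);
          out_v.push_back(acc[col]);
          acc[col] = 0.0;
        }
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["v"] = wrap(out_v));
}
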