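#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample a 3-D array onto a new grid. M is the 3x4 matrix mapping 0-based
// output voxel indices (i,j,k,1) to continuous 0-based input voxel indices.
// nearest = true for label maps; otherwise trilinear with `fill` outside.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector src_dim,
                                  NumericMatrix M, IntegerVector out_dim,
                                  bool nearest, double fill) {
  const int nx = src_dim[0], ny = src_dim[1], nz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *s = src.begin();
  double *o = out.begin();

  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i) {
        double x = M(0,0)*i + M(0,1)*j + M(0,2)*k + M(0,3);
        double y = M(1,0)*i + M(1,1)*j + M(1,2)*k + M(1,3);
        double z = M(2,0)*i + M(2,1)*j + M(2,2)*k + M(2,3);
        R_xlen_t oi = (R_xlen_t)i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k);
        if (nearest) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y),
              zi = (int)std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
            o[oi] = fill;
          } else {
            o[oi] = s[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
          }
        } else {
          // snap to the lattice when within rounding error so that grids that
          // coincide reproduce input values exactly
          const double eps = 1e-9;
          if (std::fabs(x - std::round(x)) < eps) x = std::round(x);
          if (std::fabs(y - std::round(y)) < eps) y = std::round(y);
          if (std::fabs(z - std::round(z)) < eps) z = std::round(z);
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          if (x0 < -1 || y0 < -1 || z0 < -1 || x0 > nx - 1 || y0 > ny - 1 ||
              z0 > nz - 1) {
            o[oi] = fill;
            continue;
          }
          double acc = 0.0;
          bool any = false;
          for (int dz = 0; dz <= 1; ++dz) {
            int zz = z0 + dz;
            double wz = dz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int dy = 0; dy <= 1; ++dy) {
              int yy = y0 + dy;
              double wy = dy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int dx = 0; dx <= 1; ++dx) {
                int xx = x0 + dx;
                double wx = dx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                double v;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                    zz >= nz) {
                  v = fill;
                } else {
                  v = s[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
                  any = true;
                }
                acc += wx * wy * wz * v;
              }
            }
          }
          o[oi] = any ? acc : fill;
        }
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// Joint intensity histogram with linear partial-volume weighting (each sample
// spreads over the two adjacent bins on each axis). Non-finite pairs skipped.
// [[Rcpp::export]]
NumericMatrix joint_hist_pv_cpp(NumericVector x, NumericVector y, int nbins,
                                double xmin, double xmax, double ymin,
                                double ymax) {
  NumericMatrix h(nbins, nbins);
  const double xr = (xmax > xmin) ? (nbins - 1) / (xmax - xmin) : 0.0;
  const double yr = (ymax > ymin) ? (nbins - 1) / (ymax - ymin) : 0.0;
  R_xlen_t n = x.size();
  for (R_xlen_t t = 0; t < n; ++t) {
    double xv = x[t], yv = y[t];
    if (!R_finite(xv) || !R_finite(yv)) continue;
    double px = (xv - xmin) * xr, py = (yv - ymin) * yr;
    if (px < 0) px = 0; if (px > nbins - 1) px = nbins - 1;
    if (py < 0) py = 0; if (py > nbins - 1) py = nbins - 1;
    int ix = (int)std::floor(px), iy = (int)std::floor(py);
    if (ix == nbins - 1) ix = nbins - 2;
    if (iy == nbins - 1) iy = nbins - 2;
    double fx = px - ix, fy = py - iy;
    h(ix,     iy)     += (1 - fx) * (1 - fy);
    h(ix + 1, iy)     += fx * (1 - fy);
    h(ix,     iy + 1) += (1 - fx) * fy;
    h(ix + 1, iy + 1) += fx * fy;
  }
  return h;
}

// Convolve a 3-D array along one axis (0,1,2) with a centred odd-length
// kernel, zero boundary (values outside the grid contribute nothing).
// [[Rcpp::export]]
NumericVector conv3_axis_cpp(NumericVector src, IntegerVector dim,
                             NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size();
  const int half = kl / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *s = src.begin();
  const double *kw = kernel.begin();
  double *o = out.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i * sx + j * sy + k * sz;
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        double acc = 0.0;
        int tlo = std::max(0, pos - half) - pos;
        int thi = std::min(nax - 1, pos + half) - pos;
        for (int t = tlo; t <= thi; ++t) {
          acc += kw[half + t] * s[idx + (R_xlen_t)t * stride];
        }
        o[idx] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Per-label sum and count of intensities; labels are non-negative integers.
// [[Rcpp::export]]
List label_stats_cpp(NumericVector vals, IntegerVector labs, int max_label) {
  NumericVector sums(max_label + 1);
  NumericVector counts(max_label + 1);
  R_xlen_t n = vals.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = labs[i];
    if (l < 0 || l > max_label) continue;
    sums[l] += vals[i];
    counts[l] += 1.0;
  }
  return List::create(_["sum"] = sums, _["count"] = counts);
}
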