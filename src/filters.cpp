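#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Local Shannon entropy over a disk neighbourhood.
// x: matrix already quantized to integer levels in [0, levels-1]; values < 0
// mark invalid pixels (excluded from every window). Returns entropy in bits.
// [[Rcpp::export(name = ".entropy_disk_cpp")]]
NumericMatrix entropy_disk_cpp(IntegerMatrix x, int radius, int levels) {
  const int nx = x.nrow(), ny = x.ncol();
  NumericMatrix out(nx, ny);
  // precompute disk offsets
  std::vector<int> di, dj;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { di.push_back(a); dj.push_back(b); }
  const int noff = (int)di.size();
  std::vector<int> hist(levels);
  const double log2e = 1.0 / std::log(2.0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (x(i, j) < 0) { out(i, j) = NA_REAL; continue; }
      std::fill(hist.begin(), hist.end(), 0);
      int n = 0;
      for (int k = 0; k < noff; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int v = x(ii, jj);
        if (v < 0) continue;
        ++hist[v]; ++n;
      }
      double h = 0.0;
      if (n > 0) {
        for (int v = 0; v < levels; ++v) {
          if (hist[v] == 0) continue;
          double p = (double)hist[v] / n;
          h -= p * std::log(p) * log2e;
        }
      }
      out(i, j) = h;
    }
  }
  return out;
}

// Grayscale morphological reconstruction by dilation (Vincent 1993 hybrid
// algorithm, 8-connectivity): marker <= mask assumed elementwise.
// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericMatrix reconstruct_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int nx = marker.nrow(), ny = marker.ncol();
  NumericMatrix J = clone(marker);
  const int di[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dj[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  // raster sweep (N+ neighbours: scanned before current in raster order)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double m = J(i, j);
      if (i > 0 && J(i - 1, j) > m) m = J(i - 1, j);
      if (j > 0) {
        if (J(i, j - 1) > m) m = J(i, j - 1);
        if (i > 0 && J(i - 1, j - 1) > m) m = J(i - 1, j - 1);
        if (i + 1 < nx && J(i + 1, j - 1) > m) m = J(i + 1, j - 1);
      }
      if (m > mask(i, j)) m = mask(i, j);
      J(i, j) = m;
    }
  // anti-raster sweep, enqueue boundary pixels
  std::queue<std::pair<int, int> > q;
  for (int j = ny - 1; j >= 0; --j)
    for (int i = nx - 1; i >= 0; --i) {
      double m = J(i, j);
      if (i + 1 < nx && J(i + 1, j) > m) m = J(i + 1, j);
      if (j + 1 < ny) {
        if (J(i, j + 1) > m) m = J(i, j + 1);
        if (i + 1 < nx && J(i + 1, j + 1) > m) m = J(i + 1, j + 1);
        if (i > 0 && J(i - 1, j + 1) > m) m = J(i - 1, j + 1);
      }
      if (m > mask(i, j)) m = mask(i, j);
      J(i, j) = m;
      // queue if some N- neighbour could still be raised
      bool push = false;
      if (i + 1 < nx && J(i + 1, j) < J(i, j) && J(i + 1, j) < mask(i + 1, j)) push = true;
      if (!push && j + 1 < ny) {
        if (J(i, j + 1) < J(i, j) && J(i, j + 1) < mask(i, j + 1)) push = true;
        if (!push && i + 1 < nx && J(i + 1, j + 1) < J(i, j) && J(i + 1, j + 1) < mask(i + 1, j + 1)) push = true;
        if (!push && i > 0 && J(i - 1, j + 1) < J(i, j) && J(i - 1, j + 1) < mask(i - 1, j + 1)) push = true;
      }
      if (push) q.push(std::make_pair(i, j));
    }
  while (!q.empty()) {
    int i = q.front().first, j = q.front().second;
    q.pop();
    for (int k = 0; k < 8; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        double v = J(i, j) < mask(ii, jj) ? J(i, j) : mask(ii, jj);
        if (v > J(ii, jj)) { J(ii, jj) = v; q.push(std::make_pair(ii, jj)); }
      }
    }
  }
  return J;
}

// Rigid warp with bilinear interpolation. Applies transform
// T(q) = R(theta) (q - c) + c + (dx, dy) to the image: out(p) = img(T^-1(p)).
// Coordinates are pixel units, pixel centres at (i + 0.5, j + 0.5), i along
// rows of the matrix (x), j along columns (y). Out-of-frame source pixels
// and pixels interpolating from NA become NA.
// [[Rcpp::export(name = ".warp_rigid_cpp")]]
NumericMatrix warp_rigid_cpp(NumericMatrix img, double dx, double dy,
                             double theta_deg, double cx, double cy) {
  const int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(nx, ny);
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < ny; ++j) {
    double py = j + 0.5;
    for (int i = 0; i < nx; ++i) {
      double px = i + 0.5;
      // inverse: q = R(-theta) (p - d - c) + c
      double ux = px - dx - cx, uy = py - dy - cy;
      double qx = ct * ux + st * uy + cx;
      double qy = -st * ux + ct * uy + cy;
      double fx = qx - 0.5, fy = qy - 0.5; // fractional source index
      int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
      double ax = fx - i0, ay = fy - j0;
      if (i0 < 0 || j0 < 0 || i0 + 1 >= nx || j0 + 1 >= ny) {
        out(i, j) = NA_REAL;
        continue;
      }
      double v00 = img(i0, j0), v10 = img(i0 + 1, j0);
      double v01 = img(i0, j0 + 1), v11 = img(i0 + 1, j0 + 1);
      if (ISNA(v00) || ISNA(v10) || ISNA(v01) || ISNA(v11)) {
        out(i, j) = NA_REAL;
        continue;
      }
      out(i, j) = (1 - ax) * (1 - ay) * v00 + ax * (1 - ay) * v10 +
                  (1 - ax) * ay * v01 + ax * ay * v11;
    }
  }
  return out;
}

// Separable Gaussian blur, reflecting boundary, kernel radius ceil(3 sigma).
// [[Rcpp::export(name = ".sepgauss_cpp")]]
NumericMatrix sepgauss_cpp(NumericMatrix x, double sigma) {
  const int nx = x.nrow(), ny = x.ncol();
  if (sigma <= 0) return clone(x);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;
  NumericMatrix tmp(nx, ny), out(nx, ny);
  // along x (rows)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double a = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nx) ii = 2 * nx - ii - 1;
        a += k[t + r] * x(ii, j);
      }
      tmp(i, j) = a;
    }
  // along y (cols)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double a = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= ny) jj = 2 * ny - jj - 1;
        a += k[t + r] * tmp(i, jj);
      }
      out(i, j) = a;
    }
  return out;
}

// Block means over bx x by tiles (NA -> fill value).
// [[Rcpp::export(name = ".block_mean_cpp")]]
NumericMatrix block_mean_cpp(NumericMatrix x, int bx, int by, double fill) {
  const int nx = x.nrow(), ny = x.ncol();
  const int gx = (nx + bx - 1) / bx, gy = (ny + by - 1) / by;
  NumericMatrix sum(gx, gy);
  IntegerMatrix cnt(gx, gy);
  for (int j = 0; j < ny; ++j) {
    int gj = j / by;
    for (int i = 0; i < nx; ++i) {
      double v = x(i, j);
      if (ISNA(v)) v = fill;
      sum(i / bx, gj) += v;
      cnt(i / bx, gj) += 1;
    }
  }
  for (int j = 0; j < gy; ++j)
    for (int i = 0; i < gx; ++i) sum(i, j) /= cnt(i, j);
  return sum;
}

// Bilinear upsample of a coarse block grid back to full resolution.
// Anchors sit at the true centres of the (possibly clipped) blocks; edges
// are clamped.
// [[Rcpp::export(name = ".upsample_bilinear_cpp")]]
NumericMatrix upsample_bilinear_cpp(NumericMatrix bm, int bx, int by,
                                    int nx, int ny) {
  const int gx = bm.nrow(), gy = bm.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> cx(gx), cy(gy);
  for (int i = 0; i < gx; ++i) {
    double hi = std::min((double)(i + 1) * bx, (double)nx);
    cx[i] = (i * (double)bx + hi) / 2.0;
  }
  for (int j = 0; j < gy; ++j) {
    double hi = std::min((double)(j + 1) * by, (double)ny);
    cy[j] = (j * (double)by + hi) / 2.0;
  }
  for (int j = 0; j < ny; ++j) {
    double py = j + 0.5;
    int j0 = 0;
    while (j0 < gy - 2 && cy[j0 + 1] < py) ++j0;
    // no clamping: the outer half-blocks extrapolate the edge gradient
    double wy = gy > 1 ? (py - cy[j0]) / (cy[j0 + 1] - cy[j0]) : 0;
    int j1 = gy > 1 ? j0 + 1 : j0;
    for (int i = 0; i < nx; ++i) {
      double px = i + 0.5;
      int i0 = 0;
      while (i0 < gx - 2 && cx[i0 + 1] < px) ++i0;
      double wx = gx > 1 ? (px - cx[i0]) / (cx[i0 + 1] - cx[i0]) : 0;
      int i1 = gx > 1 ? i0 + 1 : i0;
      out(i, j) = (1 - wx) * (1 - wy) * bm(i0, j0) +
                  wx * (1 - wy) * bm(i1, j0) +
                  (1 - wx) * wy * bm(i0, j1) + wx * wy * bm(i1, j1);
    }
  }
  return out;
}

// Box sum over a (2r+1)^2 window, zero padding outside, separable two-pass.
// [[Rcpp::export(name = ".box_sum_cpp")]]
NumericMatrix box_sum_cpp(NumericMatrix x, int r) {
  const int nx = x.nrow(), ny = x.ncol();
  NumericMatrix tmp(nx, ny), out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    double run = 0;
    for (int i = 0; i < nx && i <= r; ++i) run += x(i, j);
    for (int i = 0; i < nx; ++i) {
      tmp(i, j) = run;
      int add = i + r + 1, sub = i - r;
      if (add < nx) run += x(add, j);
      if (sub >= 0) run -= x(sub, j);
    }
  }
  for (int i = 0; i < nx; ++i) {
    double run = 0;
    for (int j = 0; j < ny && j <= r; ++j) run += tmp(i, j);
    for (int j = 0; j < ny; ++j) {
      out(i, j) = run;
      int add = j + r + 1, sub = j - r;
      if (add < ny) run += tmp(i, add);
      if (sub >= 0) run -= tmp(i, sub);
    }
  }
  return out;
}
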