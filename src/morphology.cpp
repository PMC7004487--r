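#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric reflection of an out-of-range index into [0, n-1].
// -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2 (half-sample symmetric).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2D median filter over a disk neighbourhood (dx^2 + dy^2 <= r^2),
// edges handled by symmetric reflection.
// [[Rcpp::export]]
NumericMatrix cpp_median_disk(NumericMatrix img, int radius) {
  const int ny = img.nrow(), nx = img.ncol();
  std::vector<int> offy, offx;
  const int r2 = radius * radius;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= r2) { offy.push_back(dy); offx.push_back(dx); }
  const int k = (int)offy.size();
  NumericMatrix out(ny, nx);
  std::vector<double> buf(k);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int j = 0; j < k; ++j) {
        int yy = reflect_idx(y + offy[j], ny);
        int xx = reflect_idx(x + offx[j], nx);
        buf[j] = img(yy, xx);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        // even count: mean of the two central order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = (lo + med) / 2.0;
      }
      out(y, x) = med;
    }
  }
  return out;
}

// 8-connected component labeling of a logical matrix (BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  const int ny = m.nrow(), nx = m.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<int> qy, qx;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0) {
      if (!m(y0, x0) || lab(y0, x0) != 0) continue;
      ++next;
      qy.clear(); qx.clear();
      qy.push_back(y0); qx.push_back(x0);
      lab(y0, x0) = next;
      while (!qy.empty()) {
        int y = qy.back(), x = qx.back();
        qy.pop_back(); qx.pop_back();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int yy = y + dy, xx = x + dx;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (m(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              qy.push_back(yy); qx.push_back(xx);
            }
          }
      }
    }
  return lab;
}

// Ball height profile per column offset dx: heights h(dx, dy) for
// dy in [-ry(dx), ry(dx)], with b(d) = sqrt(r^2 - |d|^2) - r (b(0) = 0).
struct BallSE {
  int radius;
  std::vector<int> ry;                      // per |dx| vertical half-extent
  std::vector< std::vector<double> > h;     // per dx (0..r), heights by dy
};

static BallSE make_ball(int radius) {
  BallSE se;
  se.radius = radius;
  const double r = (double)radius;
  for (int dx = 0; dx <= radius; ++dx) {
    int ry = (int)std::floor(std::sqrt(r * r - (double)dx * dx) + 1e-9);
    se.ry.push_back(ry);
    std::vector<double> col(2 * ry + 1);
    for (int dy = -ry; dy <= ry; ++dy) {
      double d2 = (double)(dy * dy + dx * dx);
      col[dy + ry] = std::sqrt(r * r - d2) - r;
    }
    se.h.push_back(col);
  }
  return se;
}

// erode = true:  out(y,x) = min over SE of img(y+dy, x+dx) - h
// erode = false: out(y,x) = max over SE of img(y+dy, x+dx) + h
static void ball_pass(const double* img, double* out, int ny, int nx,
                      const BallSE& se, bool erode) {
  const int r = se.radius;
  for (int x = 0; x < nx; ++x) {
    int dx_lo = std::max(-r, -x), dx_hi = std::min(r, nx - 1 - x);
    for (int y = 0; y < ny; ++y) {
      double m = erode ? R_PosInf : R_NegInf;
      for (int dx = dx_lo; dx <= dx_hi; ++dx) {
        int ax = dx < 0 ? -dx : dx;
        int ry = se.ry[ax];
        int dy_lo = std::max(-ry, -y), dy_hi = std::min(ry, ny - 1 - y);
        const double* p = img + (size_t)(x + dx) * ny + (y + dy_lo);
        const double* hh = &se.h[ax][dy_lo + ry];
        int n = dy_hi - dy_lo + 1;
        if (erode) {
          for (int i = 0; i < n; ++i) {
            double v = p[i] - hh[i];
            if (v < m) m = v;
          }
        } else {
          for (int i = 0; i < n; ++i) {
            double v = p[i] + hh[i];
            if (v > m) m = v;
          }
        }
      }
      out[(size_t)x * ny + y] = m;
    }
  }
}

// Grey-scale opening with a non-flat ball structuring element of the given
// radius: b(d) = sqrt(r^2 - |d|^2) - r over the disk |d| <= r (so b(0) = 0,
// b <= 0 elsewhere).  Out-of-bounds support positions are skipped.  The
// opening is a lower envelope of the image and serves as the rolling-ball
// background estimate.
// [[Rcpp::export]]
NumericMatrix cpp_ball_opening(NumericMatrix img, int radius) {
  const int ny = img.nrow(), nx = img.ncol();
  BallSE se = make_ball(radius);
  NumericMatrix ero(ny, nx), out(ny, nx);
  ball_pass(&img[0], &ero[0], ny, nx, se, true);
  ball_pass(&ero[0], &out[0], ny, nx, se, false);
  return out;
}
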