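#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sparse pyramidal Lucas-Kanade tracking of a point set between two
// grayscale frames. Frames are R matrices indexed [y, x] (column-major),
// coordinates are 0-based pixel positions (x right, y down).

struct Img {
  std::vector<double> v;
  int h, w;
  double at(int y, int x) const {
    if (y < 0) y = 0; if (y >= h) y = h - 1;
    if (x < 0) x = 0; if (x >= w) x = w - 1;
    return v[(size_t)x * h + y];
  }
  double bilin(double x, double y) const {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double fx = x - x0, fy = y - y0;
    return (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x0 + 1)
         + (1 - fx) * fy * at(y0 + 1, x0) + fx * fy * at(y0 + 1, x0 + 1);
  }
};

static Img downsample(const Img& src) {
  Img out;
  out.h = src.h / 2; out.w = src.w / 2;
  out.v.resize((size_t)out.h * out.w);
  for (int x = 0; x < out.w; ++x)
    for (int y = 0; y < out.h; ++y)
      out.v[(size_t)x * out.h + y] =
        0.25 * (src.at(2 * y, 2 * x) + src.at(2 * y + 1, 2 * x) +
                src.at(2 * y, 2 * x + 1) + src.at(2 * y + 1, 2 * x + 1));
  return out;
}

static std::vector<Img> pyramid(const NumericMatrix& m, int levels) {
  std::vector<Img> pyr(levels);
  pyr[0].h = m.nrow(); pyr[0].w = m.ncol();
  pyr[0].v.assign(m.begin(), m.end());
  for (int l = 1; l < levels; ++l) pyr[l] = downsample(pyr[l - 1]);
  return pyr;
}

// [[Rcpp::export(name = ".lk_track_pair")]]
NumericMatrix lk_track_pair(NumericMatrix prev, NumericMatrix cur,
                            NumericMatrix pts, int win = 21, int levels = 3,
                            int max_iter = 30, double eps = 0.01,
                            double min_eig = 0.5, double max_resid = 25.0) {
  const int n = pts.nrow();
  const int hw = win / 2;
  NumericMatrix out(n, 3);  // x, y, valid

  // cap pyramid depth so the coarsest level still holds the window
  int maxlev = 1;
  { int h = prev.nrow(), w = prev.ncol();
    while (maxlev < levels && (h / 2) > win && (w / 2) > win) {
      h /= 2; w /= 2; ++maxlev; } }
  levels = maxlev;

  std::vector<Img> P = pyramid(prev, levels), C = pyramid(cur, levels);
  const int npix = win * win;
  std::vector<double> T(npix), Ix(npix), Iy(npix);

  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double gx = 0, gy = 0;          // flow guess propagated across levels
    bool ok = true;
    double resid = 0;

    for (int l = levels - 1; l >= 0 && ok; --l) {
      double s = std::pow(2.0, l);
      double cx = px / s, cy = py / s;
      const Img& A = P[l];
      const Img& B = C[l];

      // template and gradients from the previous frame
      double gxx = 0, gxy = 0, gyy = 0;
      int k = 0;
      for (int u = -hw; u <= hw; ++u)
        for (int v = -hw; v <= hw; ++v, ++k) {
          double xs = cx + u, ys = cy + v;
          T[k]  = A.bilin(xs, ys);
          Ix[k] = 0.5 * (A.bilin(xs + 1, ys) - A.bilin(xs - 1, ys));
          Iy[k] = 0.5 * (A.bilin(xs, ys + 1) - A.bilin(xs, ys - 1));
          gxx += Ix[k] * Ix[k]; gxy += Ix[k] * Iy[k]; gyy += Iy[k] * Iy[k];
        }
      double tr = gxx + gyy;
      double det = gxx * gyy - gxy * gxy;
      double lmin = 0.5 * (tr - std::sqrt(std::max(0.0, tr * tr - 4 * det)));
      if (lmin / npix < min_eig) { ok = false; break; }

      double nx = 0, ny = 0;        // refinement at this level
      for (int it = 0; it < max_iter; ++it) {
        double bx = 0, by = 0;
        resid = 0;
        k = 0;
        for (int u = -hw; u <= hw; ++u)
          for (int v = -hw; v <= hw; ++v, ++k) {
            double d = T[k] - B.bilin(cx + gx + nx + u, cy + gy + ny + v);
            bx += d * Ix[k]; by += d * Iy[k];
            resid += std::fabs(d);
          }
        double dx = (gyy * bx - gxy * by) / det;
        double dy = (gxx * by - gxy * bx) / det;
        nx += dx; ny += dy;
        if (std::sqrt(dx * dx + dy * dy) < eps) break;
      }
      gx += nx; gy += ny;
      if (l > 0) { gx *= 2; gy *= 2; }
    }

    double qx = px + gx, qy = py + gy;
    if (ok && (!std::isfinite(qx) || !std::isfinite(qy))) ok = false;
    if (ok) {
      resid /= npix;
      if (resid > max_resid) ok = false;
      if (qx < 1 || qy < 1 || qx > prev.ncol() - 2 || qy > prev.nrow() - 2)
        ok = false;
    }
    out(i, 0) = ok ? qx : px;
    out(i, 1) = ok ? qy : py;
    out(i, 2) = ok ? 1.0 : 0.0;
  }
  return out;
}
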