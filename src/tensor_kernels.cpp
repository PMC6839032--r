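// Raster helpers shared by the synthetic generator, augmentation and the
// inference pipeline: bilinear resize/rotation of R image arrays and
// polyline stroke rendering. Arrays are (H, W, C[, N]), column-major.

#include <Rcpp.h>
using namespace Rcpp;

static inline size_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (size_t)h + (size_t)H * ((size_t)w + (size_t)W * ((size_t)c + (size_t)C * n));
}

// Bilinear resize (half-pixel-centre mapping, edges clamped) of (H,W,C,N).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> hw(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    hw[i] = s - h0[i];
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> ww(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    ww[j] = s - w0[j];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + idx4(0, 0, c, n, H, W, C);
      double* q = y.begin() + idx4(0, 0, c, n, Ho, Wo, C);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double a = p[(size_t)h0[i] + (size_t)H * w0[j]];
          double b = p[(size_t)h1[i] + (size_t)H * w0[j]];
          double cc = p[(size_t)h0[i] + (size_t)H * w1[j]];
          double d = p[(size_t)h1[i] + (size_t)H * w1[j]];
          double top = a * (1 - hw[i]) + b * hw[i];
          double bot = cc * (1 - hw[i]) + d * hw[i];
          q[(size_t)i + (size_t)Ho * j] = top * (1 - ww[j]) + bot * ww[j];
        }
    }
  return y;
}

// Rotate an (H,W,C) image about its centre by `degrees` (counter-clockwise in
// the x-right / y-down image frame), constant fill. Sampling is bilinear, or
// nearest-neighbour when `nearest` is set (used for binary label masks so
// thin strokes are not eroded by interpolation + thresholding). The centre
// (H/2, W/2) is used so the same angle applied at full and half resolution
// keeps image and targets aligned.
// [[Rcpp::export]]
NumericVector cpp_rotate_bilinear(NumericVector x, double degrees,
                                  NumericVector fill, bool nearest = false) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd.size() >= 3 ? xd[2] : 1;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  double th = degrees * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cy = H / 2.0, cx = W / 2.0;
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + (size_t)H * W * c;
    double* q = y.begin() + (size_t)H * W * c;
    double fv = fill[c % fill.size()];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        // inverse map: rotate destination point by -theta about the centre
        double dx0 = j - cx, dy0 = i - cy;
        double sxf = ct * dx0 + st * dy0 + cx;
        double syf = -st * dx0 + ct * dy0 + cy;
        double v;
        if (sxf < -0.5 || sxf > W - 0.5 || syf < -0.5 || syf > H - 0.5) {
          v = fv;
        } else if (nearest) {
          int xs = (int)std::lround(sxf), ys = (int)std::lround(syf);
          if (xs < 0) xs = 0;
          if (xs > W - 1) xs = W - 1;
          if (ys < 0) ys = 0;
          if (ys > H - 1) ys = H - 1;
          v = p[(size_t)ys + (size_t)H * xs];
        } else {
          int x0 = (int)std::floor(sxf), y0 = (int)std::floor(syf);
          double fx = sxf - x0, fy = syf - y0;
          double acc = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int xs = x0 + dj, ys = y0 + di;
              double wgt = (dj ? fx : 1 - fx) * (di ? fy : 1 - fy);
              double val = (xs >= 0 && xs < W && ys >= 0 && ys < H)
                             ? p[(size_t)ys + (size_t)H * xs] : fv;
              acc += wgt * val;
            }
          v = acc;
        }
        q[(size_t)i + (size_t)H * j] = v;
      }
  }
  return y;
}

// Render polyline strokes into an (H,W) coverage grid. segs is an n x 4
// matrix (x0, y0, x1, y1) in 0-based pixel coordinates (x right, y down).
// aa = TRUE gives anti-aliased coverage in [0,1]; FALSE gives a hard mask.
// [[Rcpp::export]]
NumericMatrix cpp_stroke_segments(int H, int W, NumericMatrix segs,
                                  double halfwidth, bool aa) {
  NumericMatrix out(H, W);
  double margin = halfwidth + 1.0;
  for (int s = 0; s < segs.nrow(); ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1), x1 = segs(s, 2), y1 = segs(s, 3);
    int cmin = std::max(0, (int)std::floor(std::min(x0, x1) - margin));
    int cmax = std::min(W - 1, (int)std::ceil(std::max(x0, x1) + margin));
    int rmin = std::max(0, (int)std::floor(std::min(y0, y1) - margin));
    int rmax = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + margin));
    double vx = x1 - x0, vy = y1 - y0;
    double len2 = vx * vx + vy * vy;
    for (int col = cmin; col <= cmax; ++col)
      for (int row = rmin; row <= rmax; ++row) {
        double px = col - x0, py = row - y0;
        double t = len2 > 0 ? (px * vx + py * vy) / len2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double ddx = px - t * vx, ddy = py - t * vy;
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        double cov;
        if (aa) {
          cov = halfwidth + 0.5 - d;
          if (cov < 0) cov = 0;
          if (cov > 1) cov = 1;
        } else {
          // hard mask: pixel centre must lie inside the stroke (50% coverage
          // rule), clamped so 1-px strokes stay connected
          cov = d <= std::max(halfwidth - 0.5, 0.5) ? 1.0 : 0.0;
        }
        if (cov > out(row, col)) out(row, col) = cov;
      }
  }
  return out;
}
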