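// Heuristic search over weighted pixel lattices, scanline non-maximal
// suppression, and mean-field CRF refinement.

#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct QNode {
  double f;
  unsigned long long seq;  // FIFO tie-break on equal f
  int idx;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.f != b.f) return a.f > b.f;
    return a.seq > b.seq;
  }
};

// Minimal-cost path on an 8-connected lattice. Stepping onto pixel q costs
// weights(q), multiplied by sqrt(2) for diagonal steps. goals is a logical
// mask; if heuristic_scale > 0 and there is exactly one goal pixel, an
// admissible scaled-Manhattan heuristic is used (A*), otherwise the search is
// uniform-cost (Dijkstra). 1-based (row, col) in and out.
// [[Rcpp::export]]
List cpp_grid_search(NumericMatrix weights, int start_r, int start_c,
                     LogicalMatrix goals, double heuristic_scale,
                     double diag_factor) {
  int H = weights.nrow(), W = weights.ncol();
  int sr = start_r - 1, sc = start_c - 1;
  if (sr < 0 || sr >= H || sc < 0 || sc >= W) stop("start outside grid");
  std::vector<int> goal_idx;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (goals(r, c)) goal_idx.push_back(r + H * c);
  if (goal_idx.empty()) stop("empty goal set");
  bool use_h = heuristic_scale > 0 && goal_idx.size() == 1;
  int gr = goal_idx[0] % H, gc = goal_idx[0] / H;

  std::vector<double> dist((size_t)H * W, R_PosInf);
  std::vector<int> prev((size_t)H * W, -1);
  std::vector<char> closed((size_t)H * W, 0);
  std::vector<char> is_goal((size_t)H * W, 0);
  for (int g : goal_idx) is_goal[g] = 1;

  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  unsigned long long seq = 0;
  int s = sr + H * sc;
  dist[s] = 0.0;
  double h0 = use_h ? heuristic_scale * (std::abs(sr - gr) + std::abs(sc - gc)) : 0.0;
  pq.push({h0, seq++, s});

  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const bool dg[8] = {true, false, true, false, false, true, false, true};

  int reached = -1;
  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int u = nd.idx;
    if (closed[u]) continue;
    closed[u] = 1;
    if (is_goal[u]) { reached = u; break; }
    int ur = u % H, uc = u / H;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= H || vc < 0 || vc >= W) continue;
      int v = vr + H * vc;
      if (closed[v]) continue;
      double step = weights(vr, vc) * (dg[k] ? diag_factor : 1.0);
      double nd2 = dist[u] + step;
      if (nd2 < dist[v]) {
        dist[v] = nd2;
        prev[v] = u;
        double h = use_h ? heuristic_scale * (std::abs(vr - gr) + std::abs(vc - gc)) : 0.0;
        pq.push({nd2 + h, seq++, v});
      }
    }
  }
  if (reached < 0) stop("no goal reached");  // cannot occur on finite weighted lattice
  std::vector<int> chain;
  for (int u = reached; u >= 0; u = prev[u]) chain.push_back(u);
  IntegerMatrix path(chain.size(), 2);
  for (size_t i = 0; i < chain.size(); ++i) {
    int u = chain[chain.size() - 1 - i];  // start -> goal order
    path(i, 0) = u % H + 1;
    path(i, 1) = u / H + 1;
  }
  return List::create(_["path"] = path, _["cost"] = dist[reached]);
}

// Scanline 3x3 non-maximal suppression. A pixel is kept iff its value is
// >= threshold and, within its 3x3 window, every neighbour is either
// strictly smaller or equal-valued but later in row-major scan order
// (so the first pixel of an equal plateau wins). Returns (row, col, value),
// 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_nms_scan(NumericMatrix x, double threshold) {
  int H = x.nrow(), W = x.ncol();
  std::vector<double> keep_r, keep_c, keep_v;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double v = x(r, c);
      if (v < threshold) continue;
      bool maximal = true;
      for (int dr2 = -1; dr2 <= 1 && maximal; ++dr2)
        for (int dc2 = -1; dc2 <= 1; ++dc2) {
          if (dr2 == 0 && dc2 == 0) continue;
          int nr = r + dr2, nc = c + dc2;
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          double nv = x(nr, nc);
          bool earlier = (nr < r) || (nr == r && nc < c);
          if (nv > v || (nv == v && earlier)) { maximal = false; break; }
        }
      if (maximal) {
        keep_r.push_back(r + 1);
        keep_c.push_back(c + 1);
        keep_v.push_back(v);
      }
    }
  }
  NumericMatrix out(keep_r.size(), 3);
  for (size_t i = 0; i < keep_r.size(); ++i) {
    out(i, 0) = keep_r[i];
    out(i, 1) = keep_c[i];
    out(i, 2) = keep_v[i];
  }
  return out;
}

static void gauss_blur_mat(const double* src, double* dst, int H, int W,
                           double sigma, std::vector<double>& tmp) {
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * rad + 1);
  double ssum = 0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ssum += kern[i + rad];
  }
  for (double& k : kern) k /= ssum;
  // columns (vertical pass)
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0, wsum = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0 || rr >= H) continue;
        acc += kern[i + rad] * src[(size_t)rr + (size_t)H * c];
        wsum += kern[i + rad];
      }
      tmp[(size_t)r + (size_t)H * c] = acc / wsum;
    }
  // rows (horizontal pass)
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0, wsum = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0 || cc >= W) continue;
        acc += kern[i + rad] * tmp[(size_t)r + (size_t)H * cc];
        wsum += kern[i + rad];
      }
      dst[(size_t)r + (size_t)H * c] = acc / wsum;
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  std::vector<double> tmp((size_t)H * W);
  gauss_blur_mat(x.begin(), out.begin(), H, W, sigma, tmp);
  return out;
}

// Mean-field inference for a fully-connected CRF with Potts compatibility and
// two Gaussian kernels: an appearance (bilateral) kernel over position+colour
// and a smoothness kernel over position. The bilateral message is evaluated
// over a strided window (a dense truncated window subsampled by `stride`),
// an approximation that preserves the kernel's long-range behaviour at
// tractable cost. probs: (H,W,L) normalised class probabilities; img: (H,W,3)
// in [0,1].
// [[Rcpp::export]]
NumericVector cpp_crf_meanfield(NumericVector probs, NumericVector img,
                                int iters, double sxy_app, double srgb,
                                double w_app, double sxy_sm, double w_sm,
                                int stride) {
  IntegerVector pd = probs.attr("dim");
  int H = pd[0], W = pd[1], L = pd[2];
  size_t plane = (size_t)H * W;
  std::vector<double> logU(plane * L);
  for (size_t i = 0; i < plane * L; ++i) {
    double p = probs[i];
    if (p < 1e-8) p = 1e-8;
    if (p > 1 - 1e-8) p = 1 - 1e-8;
    logU[i] = std::log(p);
  }
  NumericVector Q = clone(probs);
  std::vector<double> Msm(plane * L), Mapp(plane * L), tmp(plane);
  int rad = (int)std::ceil(2.0 * sxy_app);
  double inv2sxy = 1.0 / (2.0 * sxy_app * sxy_app);
  double inv2srgb = 1.0 / (2.0 * srgb * srgb);
  const double* R = img.begin();
  const double* G = img.begin() + plane;
  const double* B = img.begin() + 2 * plane;
  double stride_area = (double)stride * stride;

  for (int it = 0; it < iters; ++it) {
    for (int l = 0; l < L; ++l)
      gauss_blur_mat(Q.begin() + plane * l, Msm.data() + plane * l, H, W,
                     sxy_sm, tmp);
    // bilateral messages, all classes share the pairwise weights
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        size_t i = (size_t)r + (size_t)H * c;
        double acc[8] = {0};  // L <= 8 in practice (3 here)
        double wsum = 0;
        for (int dc2 = -rad; dc2 <= rad; dc2 += stride) {
          int cc = c + dc2;
          if (cc < 0 || cc >= W) continue;
          for (int dr2 = -rad; dr2 <= rad; dr2 += stride) {
            int rr = r + dr2;
            if (rr < 0 || rr >= H) continue;
            if (dr2 == 0 && dc2 == 0) continue;  // exclude self-message
            size_t j = (size_t)rr + (size_t)H * cc;
            double d2 = (double)dr2 * dr2 + (double)dc2 * dc2;
            double cr = R[i] - R[j], cg = G[i] - G[j], cb = B[i] - B[j];
            double wij = std::exp(-d2 * inv2sxy -
                                  (cr * cr + cg * cg + cb * cb) * inv2srgb) *
                         stride_area;
            wsum += wij;
            for (int l = 0; l < L; ++l) acc[l] += wij * Q[plane * l + j];
          }
        }
        for (int l = 0; l < L; ++l)
          Mapp[plane * l + i] = wsum > 0 ? acc[l] : 0.0;
      }
    }
    // Potts update: energy of label l = sum over other labels' messages
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t i = (size_t)r + (size_t)H * c;
        double tot_sm = 0, tot_app = 0;
        for (int l = 0; l < L; ++l) {
          tot_sm += Msm[plane * l + i];
          tot_app += Mapp[plane * l + i];
        }
        double mx = -1e300;
        std::vector<double> lg(L);
        for (int l = 0; l < L; ++l) {
          double pen = w_sm * (tot_sm - Msm[plane * l + i]) +
                       w_app * (tot_app - Mapp[plane * l + i]);
          lg[l] = logU[plane * l + i] - pen;
          if (lg[l] > mx) mx = lg[l];
        }
        double Z = 0;
        for (int l = 0; l < L; ++l) Z += std::exp(lg[l] - mx);
        for (int l = 0; l < L; ++l)
          Q[plane * l + i] = std::exp(lg[l] - mx) / Z;
      }
  }
  Q.attr("dim") = pd;
  return Q;
}
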