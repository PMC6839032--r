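// Single-precision activation tensors for network training/inference.
// Activations stay in C++ (externalptr) between layers; parameters remain
// double-precision R arrays (they are small and the optimizer runs in R).
// On a memory-bandwidth-bound host, halving the activation footprint roughly
// halves the cost of every convolution, normalization and pooling pass.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Freed buffers are recycled through a size-keyed pool: repeatedly
// mapping/unmapping multi-megabyte allocations costs a page-fault (and an
// implicit kernel zeroing) pass per buffer per iteration, which dominates on
// a memory-bound host. The pool is bounded; excess buffers are freed.
static std::unordered_map<size_t, std::vector<float*> > g_pool;
static size_t g_pool_bytes = 0;
static const size_t POOL_CAP_BYTES = (size_t)768 << 20;

static float* pool_get(size_t n) {
  auto it = g_pool.find(n);
  if (it != g_pool.end() && !it->second.empty()) {
    float* p = it->second.back();
    it->second.pop_back();
    g_pool_bytes -= n * sizeof(float);
    return p;
  }
  return new float[n];
}

static void pool_put(float* p, size_t n) {
  if (!p) return;
  if (g_pool_bytes + n * sizeof(float) > POOL_CAP_BYTES) {
    delete[] p;
    return;
  }
  g_pool[n].push_back(p);
  g_pool_bytes += n * sizeof(float);
}

struct FTen {
  float* p;
  int d[4];
  FTen() : p(nullptr) {}
  ~FTen() { pool_put(p, size()); }
  size_t size() const { return (size_t)d[0] * d[1] * d[2] * d[3]; }
  float* data() { return p; }
  const float* data() const { return p; }
  float& operator[](size_t i) { return p[i]; }
  float operator[](size_t i) const { return p[i]; }
};

typedef XPtr<FTen> FPtr;

// Buffers are allocated uninitialized; kernels that scatter-add request an
// explicitly zeroed buffer.
static FPtr make_ften(int d0, int d1, int d2, int d3, bool zero = false) {
  FTen* t = new FTen();
  t->d[0] = d0; t->d[1] = d1; t->d[2] = d2; t->d[3] = d3;
  t->p = pool_get(t->size());
  if (zero) std::fill(t->p, t->p + t->size(), 0.0f);
  return FPtr(t, true);
}

// [[Rcpp::export]]
void ft_pool_clear() {
  for (auto& kv : g_pool)
    for (float* p : kv.second) delete[] p;
  g_pool.clear();
  g_pool_bytes = 0;
}

// Persistent scratch memory for im2col/col2im matrices.
static float* scratch_buf(int which, size_t n) {
  static std::vector<float> bufs[4];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which].data();
}

static inline size_t fidx(const FTen& t, int h, int w, int c, int n) {
  return (size_t)h + (size_t)t.d[0] *
         ((size_t)w + (size_t)t.d[1] * ((size_t)c + (size_t)t.d[2] * n));
}

// [[Rcpp::export]]
SEXP ft_from_array(NumericVector x) {
  IntegerVector xd = x.hasAttribute("dim") ? (IntegerVector)x.attr("dim")
                                           : IntegerVector::create((int)x.size());
  int d[4] = {1, 1, 1, 1};
  for (int i = 0; i < xd.size() && i < 4; ++i) d[i] = xd[i];
  FPtr t = make_ften(d[0], d[1], d[2], d[3]);
  float* q = t->data();
  size_t n = t->size();
  for (size_t i = 0; i < n; ++i) q[i] = (float)x[i];
  return t;
}

// [[Rcpp::export]]
NumericVector ft_to_array(SEXP xp) {
  FPtr t(xp);
  NumericVector out(no_init(t->size()));
  const float* q = t->data();
  size_t n = t->size();
  for (size_t i = 0; i < n; ++i) out[i] = q[i];
  out.attr("dim") = IntegerVector::create(t->d[0], t->d[1], t->d[2], t->d[3]);
  return out;
}

// [[Rcpp::export]]
IntegerVector ft_dims(SEXP xp) {
  FPtr t(xp);
  return IntegerVector::create(t->d[0], t->d[1], t->d[2], t->d[3]);
}

static void f_im2col(const float* xn, int H, int W, int C, int k, int stride,
                     int pad, int Ho, int Wo, float* col) {
  const size_t plane = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        float* dst = col + ((size_t)(kh + k * kw + k * k * c)) * plane;
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo * stride - pad + kw;
          float* d = dst + (size_t)wo * Ho;
          if (ws < 0 || ws >= W) {
            std::fill(d, d + Ho, 0.0f);
            continue;
          }
          const float* src = xn + (size_t)H * (ws + (size_t)W * c);
          if (stride == 1) {
            int off = kh - pad;
            int lo = std::max(0, -off), hi = std::min(Ho, H - off);
            if (lo > 0) std::fill(d, d + lo, 0.0f);
            if (hi > lo) std::copy(src + lo + off, src + hi + off, d + lo);
            if (hi < Ho) std::fill(d + hi, d + Ho, 0.0f);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hs = ho * stride - pad + kh;
              d[ho] = (hs >= 0 && hs < H) ? src[hs] : 0.0f;
            }
          }
        }
      }
}

static void f_col2im_add(const float* col, int H, int W, int C, int k,
                         int stride, int pad, int Ho, int Wo, float* dxn) {
  const size_t plane = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const float* src = col + ((size_t)(kh + k * kw + k * k * c)) * plane;
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo * stride - pad + kw;
          if (ws < 0 || ws >= W) continue;
          float* dst = dxn + (size_t)H * (ws + (size_t)W * c);
          const float* s = src + (size_t)wo * Ho;
          if (stride == 1) {
            int off = kh - pad;
            int lo = std::max(0, -off), hi = std::min(Ho, H - off);
            for (int ho = lo; ho < hi; ++ho) dst[ho + off] += s[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hs = ho * stride - pad + kh;
              if (hs >= 0 && hs < H) dst[hs] += s[ho];
            }
          }
        }
      }
}

static arma::fmat weights_to_fmat(NumericVector w, size_t rows, size_t cols) {
  arma::fmat W(rows, cols);
  for (size_t i = 0; i < rows * cols; ++i) W.memptr()[i] = (float)w[i];
  return W;
}

// [[Rcpp::export]]
SEXP ft_conv2d_fwd(SEXP xp, NumericVector w, NumericVector b, int stride,
                   int pad) {
  FPtr x(xp);
  IntegerVector wd = w.attr("dim");
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  arma::fmat Wv = weights_to_fmat(w, (size_t)k * k * C, Cout);
  FPtr y = make_ften(Ho, Wo, Cout, N);
  bool has_b = b.size() == Cout;
  bool pointwise = (k == 1 && stride == 1 && pad == 0);
  size_t per = (size_t)Ho * Wo * k * k * C;
  for (int n = 0; n < N; ++n) {
    arma::fmat Y(y->data() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo,
                 Cout, false, true);
    if (pointwise) {
      arma::fmat Xn(x->data() + fidx(*x, 0, 0, 0, n), (size_t)H * W, C,
                    false, true);
      Y = Xn * Wv;
    } else {
      arma::fmat col(scratch_buf(0, per), (size_t)Ho * Wo,
                     (size_t)k * k * C, false, true);
      f_im2col(x->data() + fidx(*x, 0, 0, 0, n), H, W, C, k, stride, pad,
               Ho, Wo, col.memptr());
      Y = col * Wv;
    }
    if (has_b)
      for (int co = 0; co < Cout; ++co) Y.col(co) += (float)b[co];
  }
  return y;
}

// [[Rcpp::export]]
List ft_conv2d_bwd(SEXP xp, NumericVector w, SEXP dyp, int stride, int pad,
                   bool has_bias) {
  FPtr x(xp), dy(dyp);
  IntegerVector wd = w.attr("dim");
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  int k = wd[0], Cout = wd[3];
  int Ho = dy->d[0], Wo = dy->d[1];
  arma::fmat Wv = weights_to_fmat(w, (size_t)k * k * C, Cout);
  bool pointwise = (k == 1 && stride == 1 && pad == 0);
  FPtr dx = make_ften(H, W, C, N, !pointwise);
  arma::fmat dWv((size_t)k * k * C, Cout, arma::fill::zeros);
  NumericVector db(has_bias ? Cout : 0);
  size_t per = (size_t)Ho * Wo * k * k * C;
  arma::fmat dcol(scratch_buf(1, pointwise ? 1 : per),
                  pointwise ? 1 : (size_t)Ho * Wo,
                  pointwise ? 1 : (size_t)k * k * C, false, true);
  for (int n = 0; n < N; ++n) {
    arma::fmat dY(dy->data() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo,
                  Cout, false, true);
    if (pointwise) {
      arma::fmat Xn(x->data() + fidx(*x, 0, 0, 0, n), (size_t)H * W, C,
                    false, true);
      arma::fmat dXn(dx->data() + fidx(*dx, 0, 0, 0, n), (size_t)H * W, C,
                     false, true);
      dWv += Xn.t() * dY;
      dXn = dY * Wv.t();
    } else {
      float* cp = scratch_buf(0, per);
      f_im2col(x->data() + fidx(*x, 0, 0, 0, n), H, W, C, k, stride, pad,
               Ho, Wo, cp);
      arma::fmat col(cp, (size_t)Ho * Wo, (size_t)k * k * C, false, true);
      dWv += col.t() * dY;
      dcol = dY * Wv.t();
      f_col2im_add(dcol.memptr(), H, W, C, k, stride, pad, Ho, Wo,
                   dx->data() + fidx(*dx, 0, 0, 0, n));
    }
    if (has_bias)
      for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
  }
  NumericVector dw(no_init(w.size()));
  dw.attr("dim") = wd;
  for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = dWv.memptr()[i];
  return List::create(_["dx"] = (SEXP)dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
SEXP ft_convt_fwd(SEXP xp, NumericVector w, NumericVector b, int stride) {
  FPtr x(xp);
  IntegerVector wd = w.attr("dim");
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  int k = wd[0], Cout = wd[3];
  if (k != stride) stop("convt: kernel must equal stride");
  int Ho = H * stride, Wo = W * stride;
  FPtr y = make_ften(Ho, Wo, Cout, N);
  bool has_b = b.size() == Cout;
  arma::fmat Wsub(C, Cout);
  arma::fmat P(scratch_buf(2, (size_t)H * W * Cout), (size_t)H * W, Cout,
               false, true);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh) {
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          Wsub(ci, co) = (float)w[(size_t)kh + k * (kw + k * ((size_t)ci + (size_t)C * co))];
      for (int n = 0; n < N; ++n) {
        arma::fmat Xn(x->data() + fidx(*x, 0, 0, 0, n), (size_t)H * W, C,
                      false, true);
        P = Xn * Wsub;
        for (int co = 0; co < Cout; ++co) {
          const float* s = P.colptr(co);
          float bb = has_b ? (float)b[co] : 0.0f;
          for (int wcol = 0; wcol < W; ++wcol) {
            float* dst = y->data() +
              fidx(*y, kh, wcol * stride + kw, co, n);
            const float* sc = s + (size_t)wcol * H;
            for (int h = 0; h < H; ++h) dst[(size_t)h * stride] = sc[h] + bb;
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
List ft_convt_bwd(SEXP xp, NumericVector w, SEXP dyp, int stride,
                  bool has_bias) {
  FPtr x(xp), dy(dyp);
  IntegerVector wd = w.attr("dim");
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  int k = wd[0], Cout = wd[3];
  FPtr dx = make_ften(H, W, C, N, true);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::fmat Wsub(C, Cout), dWsub(C, Cout);
  arma::fmat dP(scratch_buf(3, (size_t)H * W * Cout), (size_t)H * W, Cout,
                false, true);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh) {
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          Wsub(ci, co) = (float)w[(size_t)kh + k * (kw + k * ((size_t)ci + (size_t)C * co))];
      dWsub.zeros();
      for (int n = 0; n < N; ++n) {
        for (int co = 0; co < Cout; ++co) {
          float* d = dP.colptr(co);
          for (int wcol = 0; wcol < W; ++wcol) {
            const float* src = dy->data() +
              fidx(*dy, kh, wcol * stride + kw, co, n);
            float* dc = d + (size_t)wcol * H;
            for (int h = 0; h < H; ++h) dc[h] = src[(size_t)h * stride];
          }
          if (has_bias) db[co] += arma::accu(dP.col(co));
        }
        arma::fmat Xn(x->data() + fidx(*x, 0, 0, 0, n), (size_t)H * W, C,
                      false, true);
        arma::fmat dXn(dx->data() + fidx(*dx, 0, 0, 0, n), (size_t)H * W, C,
                       false, true);
        dWsub += Xn.t() * dP;
        dXn += dP * Wsub.t();
      }
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          dw[(size_t)kh + k * (kw + k * ((size_t)ci + (size_t)C * co))] = dWsub(ci, co);
    }
  return List::create(_["dx"] = (SEXP)dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List ft_bnorm_fwd(SEXP xp, NumericVector gamma, NumericVector beta,
                  NumericVector rmean, NumericVector rvar, bool training,
                  double momentum, double eps, bool relu) {
  FPtr x(xp);
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  FPtr y = make_ften(H, W, C, N);
  NumericVector mean(C), invstd(C), nrmean(clone(rmean)), nrvar(clone(rvar));
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const float* p = x->data() + fidx(*x, 0, 0, c, n);
        float s_[4] = {0, 0, 0, 0}, q_[4] = {0, 0, 0, 0};
        size_t i = 0;
        for (; i + 4 <= plane; i += 4) {
          for (int u = 0; u < 4; ++u) {
            s_[u] += p[i + u];
            q_[u] += p[i + u] * p[i + u];
          }
        }
        for (; i < plane; ++i) { s_[0] += p[i]; q_[0] += p[i] * p[i]; }
        s += (double)s_[0] + s_[1] + s_[2] + s_[3];
        s2 += (double)q_[0] + q_[1] + q_[2] + q_[3];
      }
      mu = s / m;
      var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      nrmean[c] = (1 - momentum) * rmean[c] + momentum * mu;
      double ub = m > 1 ? var * m / (m - 1) : var;
      nrvar[c] = (1 - momentum) * rvar[c] + momentum * ub;
    } else {
      mu = rmean[c];
      var = rvar[c];
    }
    double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu;
    invstd[c] = is;
    float g = (float)(gamma[c] * is), b2 = (float)(beta[c] - gamma[c] * is * mu);
    for (int n = 0; n < N; ++n) {
      const float* p = x->data() + fidx(*x, 0, 0, c, n);
      float* q = y->data() + fidx(*y, 0, 0, c, n);
      if (relu) {
        for (size_t i = 0; i < plane; ++i) {
          float v = g * p[i] + b2;
          q[i] = v > 0 ? v : 0.0f;
        }
      } else {
        for (size_t i = 0; i < plane; ++i) q[i] = g * p[i] + b2;
      }
    }
  }
  return List::create(_["y"] = (SEXP)y, _["mean"] = mean,
                      _["invstd"] = invstd, _["rmean"] = nrmean,
                      _["rvar"] = nrvar);
}

// The fused-ReLU mask is reconstructed from the pre-activation
// (gamma * xhat + beta > 0), so the forward output need not be re-read.
// [[Rcpp::export]]
List ft_bnorm_bwd(SEXP xp, NumericVector gamma, NumericVector beta,
                  NumericVector mean, NumericVector invstd, SEXP dyp,
                  bool relu) {
  FPtr x(xp), dy(dyp);
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  FPtr dx = make_ften(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], is = invstd[c], g = gamma[c];
    float fg = (float)(g * is), fb = (float)(beta[c] - g * is * mu);
    double sum_dy = 0, sum_dy_xhat = 0;
    float fmu0 = (float)mu, fis0 = (float)is;
    for (int n = 0; n < N; ++n) {
      const float* __restrict p = x->data() + fidx(*x, 0, 0, c, n);
      const float* __restrict d = dy->data() + fidx(*dy, 0, 0, c, n);
      float s_[8] = {0}, t_[8] = {0};
      size_t i = 0;
      if (relu) {
        for (; i + 8 <= plane; i += 8)
          for (int u = 0; u < 8; ++u) {
            float mk = fg * p[i + u] + fb > 0 ? 1.0f : 0.0f;
            float di = d[i + u] * mk;
            s_[u] += di;
            t_[u] += di * (p[i + u] - fmu0) * fis0;
          }
        for (; i < plane; ++i) {
          float di = fg * p[i] + fb > 0 ? d[i] : 0.0f;
          s_[0] += di;
          t_[0] += di * (p[i] - fmu0) * fis0;
        }
      } else {
        for (; i + 8 <= plane; i += 8)
          for (int u = 0; u < 8; ++u) {
            s_[u] += d[i + u];
            t_[u] += d[i + u] * (p[i + u] - fmu0) * fis0;
          }
        for (; i < plane; ++i) {
          s_[0] += d[i];
          t_[0] += d[i] * (p[i] - fmu0) * fis0;
        }
      }
      double ss = 0, tt = 0;
      for (int u = 0; u < 8; ++u) { ss += s_[u]; tt += t_[u]; }
      sum_dy += ss;
      sum_dy_xhat += tt;
    }
    dgamma[c] = sum_dy_xhat;
    dbeta[c] = sum_dy;
    float a1 = (float)(sum_dy / m), a2 = (float)(sum_dy_xhat / m);
    float gis = (float)(g * is), fmu = (float)mu, fis = (float)is;
    for (int n = 0; n < N; ++n) {
      const float* __restrict p = x->data() + fidx(*x, 0, 0, c, n);
      const float* __restrict d = dy->data() + fidx(*dy, 0, 0, c, n);
      float* __restrict q = dx->data() + fidx(*dx, 0, 0, c, n);
      if (relu) {
        for (size_t i = 0; i < plane; ++i) {
          float mk = fg * p[i] + fb > 0 ? 1.0f : 0.0f;
          float xh = (p[i] - fmu) * fis;
          q[i] = gis * (d[i] * mk - a1 - xh * a2);
        }
      } else {
        for (size_t i = 0; i < plane; ++i) {
          float xh = (p[i] - fmu) * fis;
          q[i] = gis * (d[i] - a1 - xh * a2);
        }
      }
    }
  }
  return List::create(_["dx"] = (SEXP)dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List ft_maxpool_fwd(SEXP xp) {
  FPtr x(xp);
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  int Ho = H / 2, Wo = W / 2;
  FPtr y = make_ften(Ho, Wo, C, N);
  IntegerVector amax(no_init((size_t)Ho * Wo * C * N));
  const float* xv = x->data();
  float* yv = y->data();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          float best = -1e30f;
          size_t bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              size_t i = fidx(*x, 2 * ho + dh, 2 * wo + dw2, c, n);
              if (xv[i] > best) { best = xv[i]; bi = i; }
            }
          yv[o] = best;
          amax[o] = (int)bi;
          ++o;
        }
  return List::create(_["y"] = (SEXP)y, _["argmax"] = amax);
}

// [[Rcpp::export]]
SEXP ft_maxpool_bwd(SEXP dyp, IntegerVector amax, IntegerVector xdim) {
  FPtr dy(dyp);
  FPtr dx = make_ften(xdim[0], xdim[1], xdim[2], xdim[3], true);
  size_t n = dy->size();
  const float* dv = dy->data();
  float* xv = dx->data();
  for (size_t i = 0; i < n; ++i) xv[amax[i]] += dv[i];
  return dx;
}

static void resize_coeffs(int Ho, int H, std::vector<int>& h0,
                          std::vector<int>& h1, std::vector<float>& hw) {
  double sh = (double)H / Ho;
  h0.resize(Ho); h1.resize(Ho); hw.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    hw[i] = (float)(s - h0[i]);
  }
}

// [[Rcpp::export]]
SEXP ft_resize_bilinear(SEXP xp, int Ho, int Wo) {
  FPtr x(xp);
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  FPtr y = make_ften(Ho, Wo, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<float> hw, ww;
  resize_coeffs(Ho, H, h0, h1, hw);
  resize_coeffs(Wo, W, w0, w1, ww);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* p = x->data() + fidx(*x, 0, 0, c, n);
      float* q = y->data() + fidx(*y, 0, 0, c, n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          float a = p[(size_t)h0[i] + (size_t)H * w0[j]];
          float b = p[(size_t)h1[i] + (size_t)H * w0[j]];
          float cc = p[(size_t)h0[i] + (size_t)H * w1[j]];
          float d = p[(size_t)h1[i] + (size_t)H * w1[j]];
          float top = a * (1 - hw[i]) + b * hw[i];
          float bot = cc * (1 - hw[i]) + d * hw[i];
          q[(size_t)i + (size_t)Ho * j] = top * (1 - ww[j]) + bot * ww[j];
        }
    }
  return y;
}

// [[Rcpp::export]]
SEXP ft_resize_bilinear_bwd(SEXP dyp, int H, int W) {
  FPtr dy(dyp);
  int Ho = dy->d[0], Wo = dy->d[1], C = dy->d[2], N = dy->d[3];
  FPtr dx = make_ften(H, W, C, N, true);
  std::vector<int> h0, h1, w0, w1;
  std::vector<float> hw, ww;
  resize_coeffs(Ho, H, h0, h1, hw);
  resize_coeffs(Wo, W, w0, w1, ww);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      float* q = dx->data() + fidx(*dx, 0, 0, c, n);
      const float* d = dy->data() + fidx(*dy, 0, 0, c, n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          float g = d[(size_t)i + (size_t)Ho * j];
          q[(size_t)h0[i] + (size_t)H * w0[j]] += g * (1 - hw[i]) * (1 - ww[j]);
          q[(size_t)h1[i] + (size_t)H * w0[j]] += g * hw[i] * (1 - ww[j]);
          q[(size_t)h0[i] + (size_t)H * w1[j]] += g * (1 - hw[i]) * ww[j];
          q[(size_t)h1[i] + (size_t)H * w1[j]] += g * hw[i] * ww[j];
        }
    }
  return dx;
}

// [[Rcpp::export]]
SEXP ft_relu_fwd(SEXP xp) {
  FPtr x(xp);
  FPtr y = make_ften(x->d[0], x->d[1], x->d[2], x->d[3]);
  size_t n = x->size();
  const float* xv = x->data();
  float* yv = y->data();
  for (size_t i = 0; i < n; ++i) yv[i] = xv[i] > 0 ? xv[i] : 0.0f;
  return y;
}

// [[Rcpp::export]]
SEXP ft_relu_bwd(SEXP xp, SEXP gp) {
  FPtr x(xp), g(gp);
  FPtr dx = make_ften(x->d[0], x->d[1], x->d[2], x->d[3]);
  size_t n = x->size();
  const float* xv = x->data();
  const float* gv = g->data();
  float* dv = dx->data();
  for (size_t i = 0; i < n; ++i) dv[i] = xv[i] > 0 ? gv[i] : 0.0f;
  return dx;
}

// [[Rcpp::export]]
SEXP ft_add(SEXP ap, SEXP bp) {
  FPtr a(ap), b(bp);
  FPtr y = make_ften(a->d[0], a->d[1], a->d[2], a->d[3]);
  size_t n = a->size();
  const float* av = a->data();
  const float* bv = b->data();
  float* yv = y->data();
  for (size_t i = 0; i < n; ++i) yv[i] = av[i] + bv[i];
  return y;
}

// [[Rcpp::export]]
SEXP ft_axpy_inplace(SEXP ap, SEXP bp) {
  FPtr a(ap), b(bp);
  size_t n = a->size();
  float* av = a->data();
  const float* bv = b->data();
  for (size_t i = 0; i < n; ++i) av[i] += bv[i];
  return ap;
}

// Fused multi-task loss: class-balanced binary cross-entropy on the
// segmentation logits (sigmoid applied here) plus weighted MSE on the heat
// maps, with gradients w.r.t. both heads. The segmentation weight `wseg`
// is a per-element map (in training it carries the balancing weight of
// each pixel's true class, applied to every channel at that pixel); heat
// channels carry per-channel weights. Losses are weighted pixel sums
// divided by channel count, averaged over the batch.
// [[Rcpp::export]]
List ft_multitask_loss(SEXP segp, SEXP heatp, NumericVector g,
                       NumericVector pmap, NumericVector wseg,
                       NumericVector heat_alpha) {
  FPtr seg(segp), heat(heatp);
  int H = seg->d[0], W = seg->d[1], C = seg->d[2], N = seg->d[3];
  size_t plane = (size_t)H * W;
  FPtr gseg = make_ften(H, W, C, N);
  FPtr gheat = make_ften(H, W, C, N);
  double l1 = 0, l2 = 0;
  const double eps = 1e-7;
  double norm = 1.0 / ((double)C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double hc = heat_alpha[c] * norm;
      size_t off = fidx(*seg, 0, 0, c, n);
      const float* sv = seg->data() + off;
      const float* hv = heat->data() + off;
      const double* gv = g.begin() + off;
      const double* pv = pmap.begin() + off;
      const double* wv = wseg.begin() + off;
      float* gs = gseg->data() + off;
      float* gh = gheat->data() + off;
      double a2 = 0;
      for (size_t i = 0; i < plane; ++i) {
        double sig = 1.0 / (1.0 + std::exp(-(double)sv[i]));
        double sc = sig < eps ? eps : (sig > 1 - eps ? 1 - eps : sig);
        l1 -= wv[i] * norm *
              (gv[i] * std::log(sc) + (1 - gv[i]) * std::log(1 - sc));
        gs[i] = (float)(wv[i] * norm * (sig - gv[i]));
        double diff = (double)hv[i] - pv[i];
        a2 += diff * diff;
        gh[i] = (float)(2.0 * hc * diff);
      }
      l2 += hc * a2;
    }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["gseg"] = (SEXP)gseg,
                      _["gheat"] = (SEXP)gheat);
}
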