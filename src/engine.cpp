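// Minimal single-precision CNN engine: static DAG of layers with manual
// backprop and Adam. Convolutions are im2col + BLAS sgemm (via Armadillo).
// Single-threaded and deterministic: a fixed seed fixes initialisation,
// dropout masks and therefore the whole training trajectory bit-for-bit.
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
#include <cmath>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::CharacterVector;
using Rcpp::stop;

// ---------------------------------------------------------------- tensors

// NCHW, W fastest; per-image channel planes are contiguous, so the slab of
// image n aliases an (H*W x C) column-major matrix (one column per channel).
struct Ten {
  int n = 0, c = 0, h = 0, w = 0;
  arma::fvec d;
  void resize(int n_, int c_, int h_, int w_) {
    n = n_; c = c_; h = h_; w = w_;
    size_t need = (size_t)n * c * h * w;
    if (d.n_elem != need) d.set_size(need);
  }
  size_t numel() const { return (size_t)n * c * h * w; }
  float* plane(int ni, int ci) { return d.memptr() + (((size_t)ni * c + ci) * h * w); }
  const float* plane(int ni, int ci) const { return d.memptr() + (((size_t)ni * c + ci) * h * w); }
  float* img(int ni) { return d.memptr() + ((size_t)ni * c * h * w); }
  const float* img(int ni) const { return d.memptr() + ((size_t)ni * c * h * w); }
  void zero() { d.zeros(); }
};

// ------------------------------------------------------------------- rng

struct Rng {
  std::mt19937 g;
  void seed(uint32_t s) { g.seed(s); }
  float unif() { return ((g() >> 8) + 0.5f) * (1.0f / 16777216.0f); }  // (0,1)
  float unif(float lo, float hi) { return lo + (hi - lo) * unif(); }
};

// ----------------------------------------------------------------- layers

struct Layer {
  std::vector<arma::fvec> P, G, Am, Av;  // params, grads, Adam moments
  virtual ~Layer() {}
  virtual const char* type() const = 0;
  virtual void forward(std::vector<Ten*>& in, Ten& out, bool train, Rng& rng) = 0;
  // gin tensors are pre-sized and zero/accumulated by caller contract: this
  // function must ADD its input-gradient contribution into gin[k]->d.
  virtual void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) = 0;
  virtual void init(Rng& rng) {}
  size_t nparams() const {
    size_t s = 0;
    for (auto& p : P) s += p.n_elem;
    return s;
  }
  void alloc_grads() {
    G.resize(P.size()); Am.resize(P.size()); Av.resize(P.size());
    for (size_t i = 0; i < P.size(); ++i) {
      G[i].zeros(P[i].n_elem); Am[i].zeros(P[i].n_elem); Av[i].zeros(P[i].n_elem);
    }
  }
};

static void he_uniform(arma::fvec& w, int fan_in, Rng& rng) {
  float b = std::sqrt(6.0f / (float)fan_in);
  for (size_t i = 0; i < w.n_elem; ++i) w[i] = rng.unif(-b, b);
}

// He-normal scaled by fan-out (Box-Muller on the engine RNG): the canonical
// initialisation of the EfficientNet/Xception family; keeps activation
// variance controlled through deep bottleneck stacks.
static void he_normal_fanout(arma::fvec& w, int fan_out, Rng& rng) {
  float sd = std::sqrt(2.0f / (float)fan_out);
  for (size_t i = 0; i + 1 < w.n_elem; i += 2) {
    float u1 = rng.unif(), u2 = rng.unif();
    float r = std::sqrt(-2.0f * std::log(u1));
    w[i] = sd * r * std::cos(6.2831853f * u2);
    w[i + 1] = sd * r * std::sin(6.2831853f * u2);
  }
  if (w.n_elem % 2) {
    float u1 = rng.unif(), u2 = rng.unif();
    w[w.n_elem - 1] = sd * std::sqrt(-2.0f * std::log(u1)) *
                      std::cos(6.2831853f * u2);
  }
}

// im2col: cols is (Cin*k*k) x (Ho*Wo)
static void im2col(const float* im, int C, int H, int W, int k, int s, int p,
                   int Ho, int Wo, arma::fmat& cols) {
  for (int c = 0; c < C; ++c) {
    const float* pl = im + (size_t)c * H * W;
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        int r = (c * k + ky) * k + kx;
        for (int oy = 0; oy < Ho; ++oy) {
          int iy = oy * s - p + ky;
          float* dst = cols.memptr() + r + (size_t)oy * Wo * cols.n_rows;
          if (iy < 0 || iy >= H) {
            for (int ox = 0; ox < Wo; ++ox) dst[(size_t)ox * cols.n_rows] = 0.0f;
            continue;
          }
          const float* src = pl + (size_t)iy * W;
          for (int ox = 0; ox < Wo; ++ox) {
            int ix = ox * s - p + kx;
            dst[(size_t)ox * cols.n_rows] = (ix >= 0 && ix < W) ? src[ix] : 0.0f;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::fmat& cols, int C, int H, int W, int k, int s,
                       int p, int Ho, int Wo, float* im) {
  for (int c = 0; c < C; ++c) {
    float* pl = im + (size_t)c * H * W;
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        int r = (c * k + ky) * k + kx;
        for (int oy = 0; oy < Ho; ++oy) {
          int iy = oy * s - p + ky;
          if (iy < 0 || iy >= H) continue;
          float* dst = pl + (size_t)iy * W;
          const float* src = cols.memptr() + r + (size_t)oy * Wo * cols.n_rows;
          for (int ox = 0; ox < Wo; ++ox) {
            int ix = ox * s - p + kx;
            if (ix >= 0 && ix < W) dst[ix] += src[(size_t)ox * cols.n_rows];
          }
        }
      }
    }
  }
}

struct Conv : Layer {
  int cin, cout, k, s, p; bool bias;
  arma::fmat cols;
  Conv(int ci, int co, int k_, int s_, int p_, bool b)
      : cin(ci), cout(co), k(k_), s(s_), p(p_), bias(b) {
    P.resize(bias ? 2 : 1);
    P[0].set_size((size_t)cin * k * k * cout);  // (cin*k*k) x cout col-major
    if (bias) P[1].set_size(cout);
  }
  const char* type() const { return "conv"; }
  void init(Rng& rng) {
    he_normal_fanout(P[0], cout * k * k, rng);
    if (bias) P[1].zeros();
  }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    int Ho = (x.h + 2 * p - k) / s + 1, Wo = (x.w + 2 * p - k) / s + 1;
    out.resize(x.n, cout, Ho, Wo);
    cols.set_size((size_t)cin * k * k, (size_t)Ho * Wo);
    arma::fmat Wm(P[0].memptr(), (size_t)cin * k * k, cout, false, true);
    for (int ni = 0; ni < x.n; ++ni) {
      im2col(x.img(ni), cin, x.h, x.w, k, s, p, Ho, Wo, cols);
      arma::fmat O(out.img(ni), (size_t)Ho * Wo, cout, false, true);
      O = cols.t() * Wm;
      if (bias) for (int co = 0; co < cout; ++co) O.col(co) += P[1][co];
    }
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    Ten& x = *in[0];
    int Ho = out.h, Wo = out.w;
    arma::fmat Wm(P[0].memptr(), (size_t)cin * k * k, cout, false, true);
    arma::fmat gW(G[0].memptr(), (size_t)cin * k * k, cout, false, true);
    arma::fmat gcols((size_t)cin * k * k, (size_t)Ho * Wo);
    for (int ni = 0; ni < x.n; ++ni) {
      im2col(x.img(ni), cin, x.h, x.w, k, s, p, Ho, Wo, cols);
      arma::fmat Gm(gout.img(ni), (size_t)Ho * Wo, cout, false, true);
      gW += cols * Gm;
      if (bias) {
        arma::fvec gb(G[1].memptr(), cout, false, true);
        gb += arma::sum(Gm, 0).t();
      }
      if (gin[0]) {
        gcols = Wm * Gm.t();
        col2im_add(gcols, cin, x.h, x.w, k, s, p, Ho, Wo, gin[0]->img(ni));
      }
    }
  }
};

struct DWConv : Layer {  // depthwise 3x3/5x5, stride 1 or 2, "same" padding
  int c, k, s, p;
  arma::fmat cols;
  DWConv(int c_, int k_, int s_) : c(c_), k(k_), s(s_), p(k_ / 2) {
    P.resize(1);
    P[0].set_size((size_t)c * k * k);
  }
  const char* type() const { return "dwconv"; }
  void init(Rng& rng) { he_normal_fanout(P[0], k * k, rng); }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    int Ho = (x.h + 2 * p - k) / s + 1, Wo = (x.w + 2 * p - k) / s + 1;
    out.resize(x.n, c, Ho, Wo);
    cols.set_size((size_t)k * k, (size_t)Ho * Wo);
    for (int ni = 0; ni < x.n; ++ni) {
      for (int ci = 0; ci < c; ++ci) {
        im2col(x.plane(ni, ci), 1, x.h, x.w, k, s, p, Ho, Wo, cols);
        arma::fvec wv(P[0].memptr() + (size_t)ci * k * k, (size_t)k * k, false, true);
        arma::fvec O(out.plane(ni, ci), (size_t)Ho * Wo, false, true);
        O = cols.t() * wv;
      }
    }
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    Ten& x = *in[0];
    int Ho = out.h, Wo = out.w;
    arma::fmat gcols((size_t)k * k, (size_t)Ho * Wo);
    for (int ni = 0; ni < x.n; ++ni) {
      for (int ci = 0; ci < c; ++ci) {
        im2col(x.plane(ni, ci), 1, x.h, x.w, k, s, p, Ho, Wo, cols);
        arma::fvec gv(gout.plane(ni, ci), (size_t)Ho * Wo, false, true);
        arma::fvec gw(G[0].memptr() + (size_t)ci * k * k, (size_t)k * k, false, true);
        gw += cols * gv;
        if (gin[0]) {
          arma::fvec wv(P[0].memptr() + (size_t)ci * k * k, (size_t)k * k, false, true);
          gcols = wv * gv.t();
          col2im_add(gcols, 1, x.h, x.w, k, s, p, Ho, Wo, gin[0]->plane(ni, ci));
        }
      }
    }
  }
};

struct ConvT2 : Layer {  // transposed conv, kernel 2, stride 2
  int cin, cout;
  ConvT2(int ci, int co) : cin(ci), cout(co) {
    P.resize(2);
    P[0].set_size((size_t)cin * cout * 4);  // [cin x cout] per offset (a,b)
    P[1].set_size(cout);
  }
  const char* type() const { return "convT2"; }
  void init(Rng& rng) { he_normal_fanout(P[0], cout * 4, rng); P[1].zeros(); }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, cout, x.h * 2, x.w * 2);
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni) {
      arma::fmat X(const_cast<float*>(x.img(ni)), HW, cin, false, true);
      for (int off = 0; off < 4; ++off) {
        int a = off / 2, b = off % 2;
        arma::fmat Wo(P[0].memptr() + (size_t)off * cin * cout, cin, cout, false, true);
        arma::fmat O = X * Wo;  // HW x cout
        for (int co = 0; co < cout; ++co) {
          float* pl = out.plane(ni, co);
          const float* src = O.colptr(co);
          for (int y = 0; y < x.h; ++y)
            for (int xx = 0; xx < x.w; ++xx)
              pl[(size_t)(2 * y + a) * out.w + (2 * xx + b)] = src[(size_t)y * x.w + xx];
        }
      }
      // bias added once per output pixel
      for (int co = 0; co < cout; ++co) {
        float* pl = out.plane(ni, co);
        float bv = P[1][co];
        for (size_t i = 0; i < (size_t)out.h * out.w; ++i) pl[i] += bv;
      }
    }
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    Ten& x = *in[0];
    size_t HW = (size_t)x.h * x.w;
    arma::fmat Gsub(HW, cout);
    for (int ni = 0; ni < x.n; ++ni) {
      arma::fmat X(const_cast<float*>(x.img(ni)), HW, cin, false, true);
      for (int off = 0; off < 4; ++off) {
        int a = off / 2, b = off % 2;
        for (int co = 0; co < cout; ++co) {
          const float* pl = gout.plane(ni, co);
          float* dst = Gsub.colptr(co);
          for (int y = 0; y < x.h; ++y)
            for (int xx = 0; xx < x.w; ++xx)
              dst[(size_t)y * x.w + xx] = pl[(size_t)(2 * y + a) * out.w + (2 * xx + b)];
        }
        arma::fmat gW(G[0].memptr() + (size_t)off * cin * cout, cin, cout, false, true);
        gW += X.t() * Gsub;
        if (gin[0]) {
          arma::fmat Wo(P[0].memptr() + (size_t)off * cin * cout, cin, cout, false, true);
          arma::fmat GX(gin[0]->img(ni), HW, cin, false, true);
          GX += Gsub * Wo.t();
        }
      }
      arma::fvec gb(G[1].memptr(), cout, false, true);
      for (int co = 0; co < cout; ++co) {
        const float* pl = gout.plane(ni, co);
        float sum = 0.0f;
        for (size_t i = 0; i < (size_t)out.h * out.w; ++i) sum += pl[i];
        gb[co] += sum;
      }
    }
  }
};

struct BatchNorm : Layer {
  int c; float eps, momentum;
  arma::fvec run_mean, run_var, save_mean, save_invstd;
  // accumulation mode: collect exact batch statistics for re-estimating the
  // running stats over a reference set ("precise BN")
  bool accumulate = false;
  arma::fvec acc_mean, acc_var;
  long acc_n = 0;
  BatchNorm(int c_, float eps_ = 1e-5f) : c(c_), eps(eps_), momentum(0.1f) {
    P.resize(2);
    P[0].set_size(c); P[1].set_size(c);
    run_mean.zeros(c); run_var.ones(c);
    save_mean.set_size(c); save_invstd.set_size(c);
    acc_mean.zeros(c); acc_var.zeros(c);
  }
  const char* type() const { return "bn"; }
  void init(Rng&) { P[0].ones(); P[1].zeros(); run_mean.zeros(); run_var.ones(); }
  void forward(std::vector<Ten*>& in, Ten& out, bool train, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, x.h, x.w);
    size_t HW = (size_t)x.h * x.w;
    double cnt = (double)x.n * HW;
    for (int ci = 0; ci < c; ++ci) {
      float mean, invstd;
      if (train) {
        double s = 0.0, s2 = 0.0;
        for (int ni = 0; ni < x.n; ++ni) {
          const float* pl = x.plane(ni, ci);
          for (size_t i = 0; i < HW; ++i) { s += pl[i]; s2 += (double)pl[i] * pl[i]; }
        }
        double m = s / cnt, v = s2 / cnt - m * m;
        if (v < 0) v = 0;
        mean = (float)m;
        invstd = 1.0f / std::sqrt((float)v + eps);
        // unbiased variance for running stats
        float vu = (cnt > 1) ? (float)(v * cnt / (cnt - 1)) : (float)v;
        if (accumulate) {
          acc_mean[ci] += mean;
          acc_var[ci] += vu;
        } else {
          run_mean[ci] = (1 - momentum) * run_mean[ci] + momentum * mean;
          run_var[ci] = (1 - momentum) * run_var[ci] + momentum * vu;
        }
        save_mean[ci] = mean; save_invstd[ci] = invstd;
      } else {
        mean = run_mean[ci];
        invstd = 1.0f / std::sqrt(run_var[ci] + eps);
      }
      float g = P[0][ci], b = P[1][ci];
      for (int ni = 0; ni < x.n; ++ni) {
        const float* src = x.plane(ni, ci);
        float* dst = out.plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) dst[i] = (src[i] - mean) * invstd * g + b;
      }
    }
    if (train && accumulate) ++acc_n;
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    Ten& x = *in[0];
    size_t HW = (size_t)x.h * x.w;
    double cnt = (double)x.n * HW;
    for (int ci = 0; ci < c; ++ci) {
      float mean = save_mean[ci], invstd = save_invstd[ci], g = P[0][ci];
      double sg = 0.0, sgx = 0.0;
      for (int ni = 0; ni < x.n; ++ni) {
        const float* gp = gout.plane(ni, ci);
        const float* xp = x.plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) {
          sg += gp[i];
          sgx += (double)gp[i] * (xp[i] - mean) * invstd;
        }
      }
      G[0][ci] += (float)sgx;
      G[1][ci] += (float)sg;
      if (gin[0]) {
        float k1 = (float)(sg / cnt), k2 = (float)(sgx / cnt);
        for (int ni = 0; ni < x.n; ++ni) {
          const float* gp = gout.plane(ni, ci);
          const float* xp = x.plane(ni, ci);
          float* dp = gin[0]->plane(ni, ci);
          for (size_t i = 0; i < HW; ++i) {
            float xh = (xp[i] - mean) * invstd;
            dp[i] += g * invstd * (gp[i] - k1 - xh * k2);
          }
        }
      }
    }
  }
};

enum ActKind { ACT_RELU = 0, ACT_SILU, ACT_GELU, ACT_MISH };

struct Act : Layer {
  int kind;
  Act(int k_) : kind(k_) {}
  const char* type() const { return "act"; }
  static inline float sigm(float x) { return 1.0f / (1.0f + std::exp(-x)); }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, x.h, x.w);
    size_t N = x.numel();
    const float* s = x.d.memptr();
    float* o = out.d.memptr();
    switch (kind) {
      case ACT_RELU: for (size_t i = 0; i < N; ++i) o[i] = s[i] > 0 ? s[i] : 0.0f; break;
      case ACT_SILU: for (size_t i = 0; i < N; ++i) o[i] = s[i] * sigm(s[i]); break;
      case ACT_GELU: for (size_t i = 0; i < N; ++i) o[i] = 0.5f * s[i] * (1.0f + std::erf(s[i] * 0.70710678f)); break;
      case ACT_MISH: for (size_t i = 0; i < N; ++i) {
          float sp = std::log1p(std::exp(s[i]));
          o[i] = s[i] * std::tanh(sp);
        } break;
    }
  }
  void backward(std::vector<Ten*>& in, Ten&, Ten& gout, std::vector<Ten*>& gin) {
    if (!gin[0]) return;
    Ten& x = *in[0];
    size_t N = x.numel();
    const float* s = x.d.memptr();
    const float* g = gout.d.memptr();
    float* d = gin[0]->d.memptr();
    switch (kind) {
      case ACT_RELU: for (size_t i = 0; i < N; ++i) d[i] += s[i] > 0 ? g[i] : 0.0f; break;
      case ACT_SILU: for (size_t i = 0; i < N; ++i) {
          float sg = sigm(s[i]);
          d[i] += g[i] * sg * (1.0f + s[i] * (1.0f - sg));
        } break;
      case ACT_GELU: for (size_t i = 0; i < N; ++i) {
          float ph = 0.5f * (1.0f + std::erf(s[i] * 0.70710678f));
          float pdf = 0.39894228f * std::exp(-0.5f * s[i] * s[i]);
          d[i] += g[i] * (ph + s[i] * pdf);
        } break;
      case ACT_MISH: for (size_t i = 0; i < N; ++i) {
          float sp = std::log1p(std::exp(s[i]));
          float t = std::tanh(sp), sg = sigm(s[i]);
          d[i] += g[i] * (t + s[i] * sg * (1.0f - t * t));
        } break;
    }
  }
};

struct PReLU : Layer {  // one learnable slope per channel
  int c;
  PReLU(int c_) : c(c_) { P.resize(1); P[0].set_size(c); }
  const char* type() const { return "prelu"; }
  void init(Rng&) { P[0].fill(0.25f); }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, x.h, x.w);
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < c; ++ci) {
        float a = P[0][ci];
        const float* s = x.plane(ni, ci);
        float* o = out.plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) o[i] = s[i] > 0 ? s[i] : a * s[i];
      }
  }
  void backward(std::vector<Ten*>& in, Ten&, Ten& gout, std::vector<Ten*>& gin) {
    Ten& x = *in[0];
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < c; ++ci) {
        float a = P[0][ci];
        const float* s = x.plane(ni, ci);
        const float* g = gout.plane(ni, ci);
        double ga = 0.0;
        float* d = gin[0] ? gin[0]->plane(ni, ci) : nullptr;
        for (size_t i = 0; i < HW; ++i) {
          if (s[i] > 0) { if (d) d[i] += g[i]; }
          else { if (d) d[i] += a * g[i]; ga += (double)g[i] * s[i]; }
        }
        G[0][ci] += (float)ga;
      }
  }
};

struct MaxPool : Layer {
  int k, s, p;
  std::vector<int> idx;  // argmax, per output element
  MaxPool(int k_, int s_, int p_) : k(k_), s(s_), p(p_) {}
  const char* type() const { return "maxpool"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    int Ho = (x.h + 2 * p - k) / s + 1, Wo = (x.w + 2 * p - k) / s + 1;
    out.resize(x.n, x.c, Ho, Wo);
    idx.assign(out.numel(), -1);
    size_t q = 0;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        const float* pl = x.plane(ni, ci);
        float* o = out.plane(ni, ci);
        for (int oy = 0; oy < Ho; ++oy)
          for (int ox = 0; ox < Wo; ++ox) {
            float best = -std::numeric_limits<float>::infinity();
            int bi = -1;
            for (int ky = 0; ky < k; ++ky) {
              int iy = oy * s - p + ky;
              if (iy < 0 || iy >= x.h) continue;
              for (int kx = 0; kx < k; ++kx) {
                int ix = ox * s - p + kx;
                if (ix < 0 || ix >= x.w) continue;
                float v = pl[(size_t)iy * x.w + ix];
                if (v > best) { best = v; bi = iy * x.w + ix; }
              }
            }
            o[(size_t)oy * Wo + ox] = best;
            idx[q++] = bi;
          }
      }
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    if (!gin[0]) return;
    Ten& x = *in[0];
    size_t q = 0;
    size_t HWo = (size_t)out.h * out.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        float* d = gin[0]->plane(ni, ci);
        const float* g = gout.plane(ni, ci);
        for (size_t i = 0; i < HWo; ++i, ++q)
          if (idx[q] >= 0) d[idx[q]] += g[i];
      }
  }
};

struct GAP : Layer {  // global average pool to 1x1
  const char* type() const { return "gap"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, 1, 1);
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        const float* pl = x.plane(ni, ci);
        double s = 0.0;
        for (size_t i = 0; i < HW; ++i) s += pl[i];
        *out.plane(ni, ci) = (float)(s / HW);
      }
  }
  void backward(std::vector<Ten*>& in, Ten&, Ten& gout, std::vector<Ten*>& gin) {
    if (!gin[0]) return;
    Ten& x = *in[0];
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        float g = *gout.plane(ni, ci) / (float)HW;
        float* d = gin[0]->plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) d[i] += g;
      }
  }
};

struct Sigmoid : Layer {
  const char* type() const { return "sigmoid"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, x.h, x.w);
    for (size_t i = 0; i < x.numel(); ++i) out.d[i] = 1.0f / (1.0f + std::exp(-x.d[i]));
  }
  void backward(std::vector<Ten*>&, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    if (!gin[0]) return;
    for (size_t i = 0; i < out.numel(); ++i)
      gin[0]->d[i] += gout.d[i] * out.d[i] * (1.0f - out.d[i]);
  }
};

struct Mul : Layer {  // x * gate, gate is (n,c,1,1) broadcast over space
  const char* type() const { return "mul"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    Ten& s = *in[1];
    out.resize(x.n, x.c, x.h, x.w);
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        float g = *s.plane(ni, ci);
        const float* src = x.plane(ni, ci);
        float* dst = out.plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) dst[i] = src[i] * g;
      }
  }
  void backward(std::vector<Ten*>& in, Ten&, Ten& gout, std::vector<Ten*>& gin) {
    Ten& x = *in[0];
    Ten& s = *in[1];
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        float g = *s.plane(ni, ci);
        const float* xp = x.plane(ni, ci);
        const float* gp = gout.plane(ni, ci);
        if (gin[0]) {
          float* d = gin[0]->plane(ni, ci);
          for (size_t i = 0; i < HW; ++i) d[i] += gp[i] * g;
        }
        if (gin[1]) {
          double sum = 0.0;
          for (size_t i = 0; i < HW; ++i) sum += (double)gp[i] * xp[i];
          *gin[1]->plane(ni, ci) += (float)sum;
        }
      }
  }
};

struct Add : Layer {
  const char* type() const { return "add"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& a = *in[0];
    out.resize(a.n, a.c, a.h, a.w);
    for (size_t i = 0; i < a.numel(); ++i) out.d[i] = a.d[i] + in[1]->d[i];
  }
  void backward(std::vector<Ten*>&, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    for (int k = 0; k < 2; ++k)
      if (gin[k])
        for (size_t i = 0; i < out.numel(); ++i) gin[k]->d[i] += gout.d[i];
  }
};

struct Concat : Layer {  // channel-wise, any number of inputs
  const char* type() const { return "concat"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    int ctot = 0;
    for (auto* t : in) ctot += t->c;
    Ten& a = *in[0];
    out.resize(a.n, ctot, a.h, a.w);
    for (int ni = 0; ni < a.n; ++ni) {
      int co = 0;
      for (auto* t : in) {
        std::memcpy(out.plane(ni, co), t->img(ni),
                    sizeof(float) * (size_t)t->c * t->h * t->w);
        co += t->c;
      }
    }
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    Ten& a = *in[0];
    for (int ni = 0; ni < a.n; ++ni) {
      int co = 0;
      for (size_t k = 0; k < in.size(); ++k) {
        size_t len = (size_t)in[k]->c * in[k]->h * in[k]->w;
        if (gin[k]) {
          float* d = gin[k]->img(ni);
          const float* g = gout.plane(ni, co);
          for (size_t i = 0; i < len; ++i) d[i] += g[i];
        }
        co += in[k]->c;
      }
    }
  }
};

struct Up2 : Layer {  // bilinear x2, align_corners = false (half-pixel centres)
  arma::fmat tmp;
  const char* type() const { return "up2"; }
  // out[2i]   = 0.25*s[i-1] + 0.75*s[i]   (edge-clamped)
  // out[2i+1] = 0.75*s[i]   + 0.25*s[i+1]
  static void axis_up(const float* s, int n, float* o) {
    for (int i = 0; i < n; ++i) {
      int im = i > 0 ? i - 1 : 0, ip = i < n - 1 ? i + 1 : n - 1;
      o[2 * i] = 0.25f * s[im] + 0.75f * s[i];
      o[2 * i + 1] = 0.75f * s[i] + 0.25f * s[ip];
    }
  }
  static void axis_down_add(const float* g, int n, float* d) {  // transpose of axis_up
    for (int i = 0; i < n; ++i) {
      int im = i > 0 ? i - 1 : 0, ip = i < n - 1 ? i + 1 : n - 1;
      d[im] += 0.25f * g[2 * i];
      d[i] += 0.75f * g[2 * i] + 0.75f * g[2 * i + 1];
      d[ip] += 0.25f * g[2 * i + 1];
    }
  }
  void forward(std::vector<Ten*>& in, Ten& out, bool, Rng&) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, x.h * 2, x.w * 2);
    std::vector<float> row(2 * x.w), colin(x.h), colout(2 * x.h);
    arma::fmat mid(2 * x.w, x.h);  // width-upsampled, transposed storage
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        const float* pl = x.plane(ni, ci);
        for (int y = 0; y < x.h; ++y) axis_up(pl + (size_t)y * x.w, x.w, mid.colptr(y));
        float* o = out.plane(ni, ci);
        for (int xx = 0; xx < 2 * x.w; ++xx) {
          for (int y = 0; y < x.h; ++y) colin[y] = mid(xx, y);
          axis_up(colin.data(), x.h, colout.data());
          for (int y = 0; y < 2 * x.h; ++y) o[(size_t)y * 2 * x.w + xx] = colout[y];
        }
      }
  }
  void backward(std::vector<Ten*>& in, Ten& out, Ten& gout, std::vector<Ten*>& gin) {
    if (!gin[0]) return;
    Ten& x = *in[0];
    std::vector<float> gcol(2 * x.h), dcol(x.h);
    arma::fmat mid(2 * x.w, x.h);
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        const float* g = gout.plane(ni, ci);
        mid.zeros();
        for (int xx = 0; xx < 2 * x.w; ++xx) {
          for (int y = 0; y < 2 * x.h; ++y) gcol[y] = g[(size_t)y * 2 * x.w + xx];
          std::fill(dcol.begin(), dcol.end(), 0.0f);
          axis_down_add(gcol.data(), x.h, dcol.data());
          for (int y = 0; y < x.h; ++y) mid(xx, y) += dcol[y];
        }
        float* d = gin[0]->plane(ni, ci);
        std::vector<float> drow(x.w);
        for (int y = 0; y < x.h; ++y) {
          std::fill(drow.begin(), drow.end(), 0.0f);
          axis_down_add(mid.colptr(y), x.w, drow.data());
          float* dst = d + (size_t)y * x.w;
          for (int xx = 0; xx < x.w; ++xx) dst[xx] += drow[xx];
        }
      }
  }
};

struct Dropout2d : Layer {  // channel (spatial) dropout
  float rate;
  bool enabled = true;
  std::vector<float> mask;  // per (n, c): 0 or 1/(1-rate)
  Dropout2d(float r) : rate(r) {}
  const char* type() const { return "dropout"; }
  void forward(std::vector<Ten*>& in, Ten& out, bool train, Rng& rng) {
    Ten& x = *in[0];
    out.resize(x.n, x.c, x.h, x.w);
    size_t HW = (size_t)x.h * x.w;
    if (!train || !enabled || rate <= 0.0f) {
      std::memcpy(out.d.memptr(), x.d.memptr(), sizeof(float) * x.numel());
      mask.assign((size_t)x.n * x.c, 1.0f);
      return;
    }
    mask.resize((size_t)x.n * x.c);
    float keep = 1.0f - rate;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        float m = (rng.unif() < rate) ? 0.0f : 1.0f / keep;
        mask[(size_t)ni * x.c + ci] = m;
        const float* s = x.plane(ni, ci);
        float* o = out.plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) o[i] = s[i] * m;
      }
  }
  void backward(std::vector<Ten*>& in, Ten&, Ten& gout, std::vector<Ten*>& gin) {
    if (!gin[0]) return;
    Ten& x = *in[0];
    size_t HW = (size_t)x.h * x.w;
    for (int ni = 0; ni < x.n; ++ni)
      for (int ci = 0; ci < x.c; ++ci) {
        float m = mask[(size_t)ni * x.c + ci];
        const float* g = gout.plane(ni, ci);
        float* d = gin[0]->plane(ni, ci);
        for (size_t i = 0; i < HW; ++i) d[i] += g[i] * m;
      }
  }
};

// -------------------------------------------------------------------- net

struct Node {
  int layer;                  // -1 for the input placeholder
  std::vector<int> inputs;    // node indices
};

struct Net {
  std::vector<std::unique_ptr<Layer>> layers;
  std::vector<Node> nodes;    // topological (construction) order; node 0 = input
  std::vector<Ten> acts, grads;
  std::vector<int> outputs;   // output node ids (multiple under deep supervision)
  std::vector<bool> needs_grad;  // does any param lie upstream of this node?
  Rng rng;
  long long step = 0;

  void compute_needs_grad() {
    needs_grad.assign(nodes.size(), false);
    for (size_t i = 1; i < nodes.size(); ++i) {
      bool ng = layers[nodes[i].layer]->P.size() > 0;
      for (int in : nodes[i].inputs)
        if (in > 0 && needs_grad[in]) ng = true;
      needs_grad[i] = ng;
    }
  }

  void forward(Ten& x, bool train) {
    acts.resize(nodes.size());
    acts[0] = x;  // copy (small)
    std::vector<Ten*> ins;
    for (size_t i = 1; i < nodes.size(); ++i) {
      ins.clear();
      for (int k : nodes[i].inputs) ins.push_back(&acts[k]);
      layers[nodes[i].layer]->forward(ins, acts[i], train, rng);
    }
  }

  // gout: map node id -> gradient tensor (already sized)
  void backward(std::vector<std::pair<int, Ten*>>& gouts) {
    grads.resize(nodes.size());
    std::vector<bool> has(nodes.size(), false);
    for (auto& pr : gouts) {
      int nd = pr.first;
      grads[nd].resize(acts[nd].n, acts[nd].c, acts[nd].h, acts[nd].w);
      grads[nd].zero();
      grads[nd].d += pr.second->d;
      has[nd] = true;
    }
    std::vector<Ten*> ins, gins;
    for (int i = (int)nodes.size() - 1; i >= 1; --i) {
      if (!has[i] || !needs_grad[i]) continue;
      ins.clear(); gins.clear();
      for (int k : nodes[i].inputs) {
        ins.push_back(&acts[k]);
        if (k > 0 && needs_grad[k]) {
          if (!has[k]) {
            grads[k].resize(acts[k].n, acts[k].c, acts[k].h, acts[k].w);
            grads[k].zero();
            has[k] = true;
          }
          gins.push_back(&grads[k]);
        } else {
          gins.push_back(nullptr);
        }
      }
      layers[nodes[i].layer]->backward(ins, acts[i], grads[i], gins);
    }
  }

  void zero_grad() {
    for (auto& l : layers)
      for (auto& g : l->G) g.zeros();
  }

  void adam(float lr, float b1, float b2, float eps) {
    ++step;
    float c1 = 1.0f - std::pow(b1, (float)step);
    float c2 = 1.0f - std::pow(b2, (float)step);
    for (auto& l : layers)
      for (size_t j = 0; j < l->P.size(); ++j) {
        arma::fvec& p = l->P[j];
        arma::fvec& g = l->G[j];
        arma::fvec& m = l->Am[j];
        arma::fvec& v = l->Av[j];
        for (size_t i = 0; i < p.n_elem; ++i) {
          m[i] = b1 * m[i] + (1 - b1) * g[i];
          v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
          p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
        }
      }
  }
};

// --------------------------------------------------------- construction

static Layer* make_layer(List sp) {
  std::string t = Rcpp::as<std::string>(sp["type"]);
  auto gi = [&sp](const char* k) { return Rcpp::as<int>(sp[k]); };
  if (t == "conv")
    return new Conv(gi("cin"), gi("cout"), gi("k"), gi("stride"), gi("pad"),
                    Rcpp::as<bool>(sp["bias"]));
  if (t == "dwconv") return new DWConv(gi("c"), gi("k"), gi("stride"));
  if (t == "convT2") return new ConvT2(gi("cin"), gi("cout"));
  if (t == "bn") return new BatchNorm(gi("c"));
  if (t == "act") {
    std::string k = Rcpp::as<std::string>(sp["kind"]);
    if (k == "relu") return new Act(ACT_RELU);
    if (k == "swish") return new Act(ACT_SILU);
    if (k == "gelu") return new Act(ACT_GELU);
    if (k == "mish") return new Act(ACT_MISH);
    stop("unknown activation kind: %s", k.c_str());
  }
  if (t == "prelu") return new PReLU(gi("c"));
  if (t == "maxpool") return new MaxPool(gi("k"), gi("stride"), gi("pad"));
  if (t == "gap") return new GAP();
  if (t == "sigmoid") return new Sigmoid();
  if (t == "mul") return new Mul();
  if (t == "add") return new Add();
  if (t == "concat") return new Concat();
  if (t == "up2") return new Up2();
  if (t == "dropout") return new Dropout2d(Rcpp::as<float>(sp["rate"]));
  stop("unknown layer type: %s", t.c_str());
  return nullptr;
}

// [[Rcpp::export]]
SEXP eng_build(List layerspecs, List node_inputs, IntegerVector node_layer,
               IntegerVector output_nodes) {
  Net* net = new Net();
  for (R_xlen_t i = 0; i < layerspecs.size(); ++i) {
    net->layers.emplace_back(make_layer(layerspecs[i]));
    net->layers.back()->alloc_grads();
  }
  for (R_xlen_t i = 0; i < node_inputs.size(); ++i) {
    Node nd;
    nd.layer = node_layer[i];  // -1 for input
    IntegerVector iv = node_inputs[i];
    for (int k : iv) nd.inputs.push_back(k);
    net->nodes.push_back(nd);
  }
  for (int k : output_nodes) net->outputs.push_back(k);
  net->compute_needs_grad();
  return Rcpp::XPtr<Net>(net, true);
}

// [[Rcpp::export]]
void eng_init(SEXP ptr, int seed) {
  Rcpp::XPtr<Net> net(ptr);
  net->rng.seed((uint32_t)seed);
  for (auto& l : net->layers) l->init(net->rng);
  for (auto& l : net->layers)
    for (size_t j = 0; j < l->P.size(); ++j) { l->Am[j].zeros(); l->Av[j].zeros(); }
  net->step = 0;
}

// [[Rcpp::export]]
double eng_nparams(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  double s = 0;
  for (auto& l : net->layers) s += (double)l->nparams();
  return s;
}

// [[Rcpp::export]]
Rcpp::DataFrame eng_param_table(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<std::string> ty;
  std::vector<double> np;
  for (auto& l : net->layers) {
    ty.push_back(l->type());
    np.push_back((double)l->nparams());
  }
  return Rcpp::DataFrame::create(Rcpp::Named("type") = ty, Rcpp::Named("nparams") = np);
}

static Ten ten_from_r(NumericVector x, IntegerVector dims) {
  Ten t;
  t.resize(dims[0], dims[1], dims[2], dims[3]);
  for (size_t i = 0; i < t.numel(); ++i) t.d[i] = (float)x[i];
  return t;
}

static NumericVector ten_to_r(const Ten& t) {
  NumericVector out(t.numel());
  for (size_t i = 0; i < t.numel(); ++i) out[i] = (double)t.d[i];
  out.attr("tdim") = IntegerVector::create(t.n, t.c, t.h, t.w);
  return out;
}

// [[Rcpp::export]]
NumericVector eng_forward(SEXP ptr, NumericVector x, IntegerVector dims, bool train) {
  Rcpp::XPtr<Net> net(ptr);
  Ten tx = ten_from_r(x, dims);
  net->forward(tx, train);
  return ten_to_r(net->acts[net->outputs.back()]);
}

// [[Rcpp::export]]
List eng_node_outputs(SEXP ptr, NumericVector x, IntegerVector dims, IntegerVector nodes) {
  Rcpp::XPtr<Net> net(ptr);
  Ten tx = ten_from_r(x, dims);
  net->forward(tx, false);
  List out(nodes.size());
  for (R_xlen_t i = 0; i < nodes.size(); ++i) out[i] = ten_to_r(net->acts[nodes[i]]);
  return out;
}

// combined loss on logits z: (1-alpha)*BCE + alpha*soft-Dice, pixels pooled
// over the whole batch. Returns loss pieces; fills gz.
static void combined_loss_grad(const Ten& z, const Ten& y, double alpha,
                               double& bce, double& dice, Ten& gz) {
  size_t N = z.numel();
  const double ep = 1e-7, eps_d = 1e-6;
  double s_bce = 0.0, s_py = 0.0, s_p = 0.0, s_y = 0.0;
  std::vector<double> pv(N);
  for (size_t i = 0; i < N; ++i) {
    double p = 1.0 / (1.0 + std::exp(-(double)z.d[i]));
    pv[i] = p;
    double pc = std::min(std::max(p, ep), 1.0 - ep);
    double yy = (double)y.d[i];
    s_bce += yy * std::log(pc) + (1.0 - yy) * std::log(1.0 - pc);
    s_py += p * yy;
    s_p += p;
    s_y += yy;
  }
  bce = -s_bce / (double)N;
  double Nm = 2.0 * s_py + eps_d, D = s_p + s_y + eps_d;
  dice = 1.0 - Nm / D;
  gz.resize(z.n, z.c, z.h, z.w);
  for (size_t i = 0; i < N; ++i) {
    double p = pv[i], yy = (double)y.d[i];
    double g_bce = (p - yy) / (double)N;                       // d BCE / d z
    double ddice_dp = (Nm - 2.0 * yy * D) / (D * D);           // d Dice / d p
    double g_dice = ddice_dp * p * (1.0 - p);                  // chain sigmoid
    gz.d[i] = (float)((1.0 - alpha) * g_bce + alpha * g_dice);
  }
}

// [[Rcpp::export]]
List eng_train_step(SEXP ptr, NumericVector x, IntegerVector xdim, NumericVector y,
                    double alpha, double lr, double beta1, double beta2, double eps) {
  Rcpp::XPtr<Net> net(ptr);
  Ten tx = ten_from_r(x, xdim);
  net->forward(tx, true);
  net->zero_grad();
  double nb = (double)net->outputs.size();
  double bce_t = 0.0, dice_t = 0.0, loss_t = 0.0;
  std::vector<Ten> gts(net->outputs.size());
  std::vector<std::pair<int, Ten*>> gouts;
  for (size_t hi = 0; hi < net->outputs.size(); ++hi) {
    Ten& zt = net->acts[net->outputs[hi]];
    Ten ty;
    ty.resize(zt.n, zt.c, zt.h, zt.w);
    if ((size_t)y.size() != ty.numel()) stop("label size mismatch");
    for (size_t i = 0; i < ty.numel(); ++i) ty.d[i] = (float)y[i];
    double bce, dice;
    combined_loss_grad(zt, ty, alpha, bce, dice, gts[hi]);
    gts[hi].d *= (float)(1.0 / nb);  // heads averaged
    bce_t += bce / nb;
    dice_t += dice / nb;
    gouts.push_back({net->outputs[hi], &gts[hi]});
  }
  loss_t = (1.0 - alpha) * bce_t + alpha * dice_t;
  net->backward(gouts);
  net->adam((float)lr, (float)beta1, (float)beta2, (float)eps);
  return List::create(Rcpp::Named("loss") = loss_t, Rcpp::Named("bce") = bce_t,
                      Rcpp::Named("dice") = dice_t);
}

// [[Rcpp::export]]
List eng_eval_loss(SEXP ptr, NumericVector x, IntegerVector xdim, NumericVector y,
                   double alpha) {
  Rcpp::XPtr<Net> net(ptr);
  Ten tx = ten_from_r(x, xdim);
  net->forward(tx, false);
  Ten& zt = net->acts[net->outputs.back()];
  Ten ty;
  ty.resize(zt.n, zt.c, zt.h, zt.w);
  for (size_t i = 0; i < ty.numel(); ++i) ty.d[i] = (float)y[i];
  double bce, dice;
  Ten dummy;
  combined_loss_grad(zt, ty, alpha, bce, dice, dummy);
  return List::create(Rcpp::Named("loss") = (1.0 - alpha) * bce + alpha * dice,
                      Rcpp::Named("bce") = bce, Rcpp::Named("dice") = dice);
}

// [[Rcpp::export]]
NumericVector eng_get_params(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  size_t tot = 0;
  for (auto& l : net->layers) {
    tot += l->nparams();
    BatchNorm* bn = dynamic_cast<BatchNorm*>(l.get());
    if (bn) tot += 2 * bn->c;  // running stats travel with the checkpoint
  }
  NumericVector out(tot);
  size_t q = 0;
  for (auto& l : net->layers) {
    for (auto& p : l->P)
      for (size_t i = 0; i < p.n_elem; ++i) out[q++] = (double)p[i];
    BatchNorm* bn = dynamic_cast<BatchNorm*>(l.get());
    if (bn) {
      for (int i = 0; i < bn->c; ++i) out[q++] = (double)bn->run_mean[i];
      for (int i = 0; i < bn->c; ++i) out[q++] = (double)bn->run_var[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
void eng_set_params(SEXP ptr, NumericVector v) {
  Rcpp::XPtr<Net> net(ptr);
  size_t q = 0;
  for (auto& l : net->layers) {
    for (auto& p : l->P) {
      if (q + p.n_elem > (size_t)v.size()) stop("parameter vector too short");
      for (size_t i = 0; i < p.n_elem; ++i) p[i] = (float)v[q++];
    }
    BatchNorm* bn = dynamic_cast<BatchNorm*>(l.get());
    if (bn) {
      for (int i = 0; i < bn->c; ++i) bn->run_mean[i] = (float)v[q++];
      for (int i = 0; i < bn->c; ++i) bn->run_var[i] = (float)v[q++];
    }
  }
  if (q != (size_t)v.size()) stop("parameter vector length mismatch");
}

// Precise-BN support: between begin and finish, train-mode forwards add
// their exact batch statistics to per-layer accumulators instead of the
// exponential running average; finish replaces the running stats with the
// accumulated means.
// [[Rcpp::export]]
void eng_bn_begin_accum(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  for (auto& l : net->layers) {
    BatchNorm* bn = dynamic_cast<BatchNorm*>(l.get());
    if (bn) {
      bn->accumulate = true;
      bn->acc_mean.zeros();
      bn->acc_var.zeros();
      bn->acc_n = 0;
    }
    Dropout2d* dr = dynamic_cast<Dropout2d*>(l.get());
    if (dr) dr->enabled = false;  // statistics passes are deterministic
  }
}

// [[Rcpp::export]]
void eng_bn_finish_accum(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  for (auto& l : net->layers) {
    BatchNorm* bn = dynamic_cast<BatchNorm*>(l.get());
    if (bn) {
      if (bn->acc_n > 0) {
        bn->run_mean = bn->acc_mean / (float)bn->acc_n;
        bn->run_var = bn->acc_var / (float)bn->acc_n;
      }
      bn->accumulate = false;
    }
    Dropout2d* dr = dynamic_cast<Dropout2d*>(l.get());
    if (dr) dr->enabled = true;
  }
}

// Trainable-parameter gradients after the last backward pass (no running
// stats); used by the finite-difference tests.
// [[Rcpp::export]]
NumericVector eng_get_grads(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  size_t tot = 0;
  for (auto& l : net->layers) tot += l->nparams();
  NumericVector out(tot);
  size_t q = 0;
  for (auto& l : net->layers)
    for (auto& g : l->G)
      for (size_t i = 0; i < g.n_elem; ++i) out[q++] = (double)g[i];
  return out;
}

// Trainable parameters only (no running stats), matching eng_get_grads.
// [[Rcpp::export]]
NumericVector eng_get_trainable(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  size_t tot = 0;
  for (auto& l : net->layers) tot += l->nparams();
  NumericVector out(tot);
  size_t q = 0;
  for (auto& l : net->layers)
    for (auto& p : l->P)
      for (size_t i = 0; i < p.n_elem; ++i) out[q++] = (double)p[i];
  return out;
}

// [[Rcpp::export]]
void eng_set_trainable(SEXP ptr, NumericVector v) {
  Rcpp::XPtr<Net> net(ptr);
  size_t q = 0;
  for (auto& l : net->layers)
    for (auto& p : l->P)
      for (size_t i = 0; i < p.n_elem; ++i) p[i] = (float)v[q++];
}

// [[Rcpp::export]]
void eng_seed_rng(SEXP ptr, int seed) {
  Rcpp::XPtr<Net> net(ptr);
  net->rng.seed((uint32_t)seed);
}
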