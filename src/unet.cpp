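// Encoder-decoder (U-net style) forward and backward passes for sinogram
// completion, in single precision on top of BLAS GEMM.
//
// Feature-map layout ("halo" layout): every map of nominal size (H, W) is
// stored as an fmat of shape (C, Hp*Wp*N) with Hp = H + 2, Wp = W + 2 and a
// one-pixel zero border (halo) per image; image n occupies the column block
// [n*Pp, (n+1)*Pp) with Pp = Hp*Wp and spatial index p = x*Hp + y.
//
// With the halo in place, a 3x3 stride-1 convolution is nine shifted
// contiguous GEMM accumulations y[, q] += W_t * x[, q + o(t)] — no im2col
// at all, and all operands stay cache-resident at the shallow levels where
// an im2col buffer would be tens of megabytes.  Outputs at halo positions
// pick up garbage from neighbouring grid columns and are re-zeroed
// afterwards; interior outputs only ever read their own image's interior
// or halo, so images in a batch never contaminate each other.  Stride-2
// (down) convolutions and their adjoints (the transposed convolutions of
// the decoder) use a small gather/scatter on the coarse grid instead.
//
// Architecture (depth d, channel schedule ch[1..d] + bottleneck):
//   encoder level i: conv3x3 s1 -> lrelu, conv3x3 s1 -> lrelu (skip),
//                    conv3x3 s2 -> lrelu (down)
//   bottleneck:      two conv3x3 s1 -> lrelu
//   decoder level i: transposed conv3x3 s2 -> relu, concat skip,
//                    conv3x3 s1 -> relu
//   output:          conv3x3 s1, linear
//
// Weight layout: a conv weight is (C_out x 9*C_in); tap t = dx*3 + dy
// occupies the column block [t*C_in, (t+1)*C_in).  A transposed conv
// stores the weight of the matching stride-2 conv (C_deep x 9*C_level)
// and applies its exact adjoint.

#include <RcppArmadillo.h>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif
#ifdef __unix__
#include <dlfcn.h>
#endif
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace arma;

// Process-level knobs set once when the shared object loads:
// - keep the multi-megabyte buffers the training loop recycles every step
//   on the heap free list instead of paying mmap/munmap page faults;
// - pin OpenBLAS to one thread: GEMM reduction order then stays fixed, so
//   a seeded training run is bit-reproducible, and oversubscription on a
//   single-CPU machine is avoided;
// - flush denormal floats to zero: saturated rectifier units otherwise
//   drive single-precision gradients into the denormal range, where the
//   hardware takes a large per-operation penalty.
static int init_process_knobs() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
#ifdef __unix__
  typedef void (*set_threads_t)(int);
  set_threads_t f =
      (set_threads_t)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f) f(1);
#endif
#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  return 0;
}
static int process_knobs_done = init_process_knobs();

// ---------------------------------------------------------------- helpers

static fmat to_f(const Rcpp::NumericMatrix& m) {
  fmat f(m.nrow(), m.ncol());
  const double* s = m.begin();
  float* d = f.memptr();
  for (uword i = 0; i < f.n_elem; i++) d[i] = (float)s[i];
  return f;
}

static fvec to_fv(const Rcpp::NumericVector& v) {
  fvec f(v.size());
  for (R_xlen_t i = 0; i < v.size(); i++) f[i] = (float)v[i];
  return f;
}

static Rcpp::NumericMatrix to_d(const fmat& f) {
  Rcpp::NumericMatrix m(f.n_rows, f.n_cols);
  const float* s = f.memptr();
  double* d = m.begin();
  for (uword i = 0; i < f.n_elem; i++) d[i] = (double)s[i];
  return m;
}

static Rcpp::NumericVector to_dv(const fvec& f) {
  Rcpp::NumericVector v(f.n_elem);
  for (uword i = 0; i < f.n_elem; i++) v[i] = (double)f[i];
  return v;
}

struct Grid {
  int H, W;    // interior size
  int Hp, Wp;  // padded size
  uword Pp;    // Hp * Wp
  Grid() : H(0), W(0), Hp(0), Wp(0), Pp(0) {}
  Grid(int h, int w)
      : H(h), W(w), Hp(h + 2), Wp(w + 2), Pp((uword)(h + 2) * (w + 2)) {}
  Grid half() const { return Grid(H / 2, W / 2); }
};

// zero the one-pixel border of every image in a halo-layout map
static void zero_halo(fmat& m, int C, const Grid& g, int N) {
  float* D = m.memptr();
  const size_t cb = (size_t)C * sizeof(float);
  for (int n = 0; n < N; n++) {
    float* base = D + (uword)n * g.Pp * C;
    std::memset(base, 0, (size_t)g.Hp * cb);
    std::memset(base + (uword)(g.Wp - 1) * g.Hp * C, 0, (size_t)g.Hp * cb);
    for (int x = 1; x < g.Wp - 1; x++) {
      std::memset(base + (uword)x * g.Hp * C, 0, cb);
      std::memset(base + ((uword)x * g.Hp + g.Hp - 1) * C, 0, cb);
    }
  }
}

static void lrelu_inplace(fmat& x, float slope) {
  float* p = x.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; i++) {
    const float v = p[i];
    p[i] = v > 0 ? v : v * slope;  // branchless; vectorizes to a blend
  }
}

// grad *= activation derivative, recovered from the stored post-activation
static void act_bwd(fmat& g, const fmat& out, float slope) {
  float* p = g.memptr();
  const float* o = out.memptr();
  const uword n = g.n_elem;
  for (uword i = 0; i < n; i++) p[i] = o[i] > 0 ? p[i] : p[i] * slope;
}

// ------------------------------------------- stride-1 conv via tap GEMMs

// y (Co x Pp*N) = conv3x3(x), no bias/activation; y fully written
static void conv_core_taps(const fmat& x, int C, const fmat& W, int Co,
                           const Grid& g, int N, fmat& y) {
  const uword total = g.Pp * (uword)N;
  y.set_size(Co, total);
  {
    fmat Yv(y.memptr(), Co, total, false, true);
    const fmat Xv(const_cast<float*>(x.memptr()), C, total, false, true);
    Yv = W.cols(4 * (uword)C, 5 * (uword)C - 1) * Xv;
  }
  for (int t = 0; t < 9; t++) {
    if (t == 4) continue;
    const int dy = t % 3, dx = t / 3;
    const long long o = (long long)(dx - 1) * g.Hp + (dy - 1);
    const uword lo = (uword)std::max(0LL, -o);
    const uword hi = total - 1 - (uword)std::max(0LL, o);
    const uword len = hi - lo + 1;
    fmat Yv(y.memptr() + lo * Co, Co, len, false, true);
    const fmat Xv(const_cast<float*>(x.memptr()) + (uword)(lo + o) * C, C,
                  len, false, true);
    Yv += W.cols((uword)t * C, (uword)t * C + C - 1) * Xv;
  }
}

// materialize the 3x3 windows of a halo map as a (9C x Pp*N) matrix; the
// three vertical taps of each horizontal group are one contiguous copy.
// Positions whose window would leave the array (the all-halo ends) get
// zeros; interior windows never cross between images thanks to the halo.
static void im2col_halo(const fmat& x, int C, const Grid& g, int N,
                        fmat& cols) {
  const long long total = (long long)g.Pp * N;
  const uword crows = 9 * (uword)C;
  cols.set_size(crows, (uword)total);
  const size_t c3b = 3 * (size_t)C * sizeof(float);
  for (int dxb = 0; dxb < 3; dxb++) {
    const long long ocol = (long long)(dxb - 1) * g.Hp;
    const long long lo = std::max(0LL, 1 - ocol);
    const long long hi = std::min(total - 1, total - 2 - ocol);
    float* dst0 = cols.memptr() + (uword)(dxb * 3 * C);
    for (long long q = 0; q < lo; q++)
      std::memset(dst0 + (uword)q * crows, 0, c3b);
    for (long long q = hi + 1; q < total; q++)
      std::memset(dst0 + (uword)q * crows, 0, c3b);
    const float* src = x.memptr() + (uword)(lo + ocol - 1) * C;
    float* dst = dst0 + (uword)lo * crows;
    for (long long q = lo; q <= hi; q++) {
      std::memcpy(dst, src, c3b);
      dst += crows;
      src += C;
    }
  }
}

// weight gradient through an explicit window matrix: one wide GEMM
// instead of nine narrow ones (narrow A*B' GEMMs with a huge inner
// dimension run far below peak)
static fmat dw_cols_buf;  // persistent workspace
static void conv_dw_im2col(const fmat& g, const fmat& x, int C, int Co,
                           const Grid& gr, int N, fmat& dW) {
  im2col_halo(x, C, gr, N, dw_cols_buf);
  dW = g * dw_cols_buf.t();
}

// rearrange a conv weight (Co x 9*Ci) into the flipped-kernel,
// channel-swapped weight (Ci x 9*Co) whose forward convolution is the
// backward-input pass of the original conv
static fmat flip_weights(const fmat& W, int Ci, int Co) {
  fmat R(Ci, 9 * (uword)Co);
  for (int t = 0; t < 9; t++) {
    const int tf = 8 - t;  // (dx, dy) -> (2 - dx, 2 - dy)
    for (int co = 0; co < Co; co++)
      for (int ci = 0; ci < Ci; ci++)
        R(ci, (uword)tf * Co + co) = W(co, (uword)t * Ci + ci);
  }
  return R;
}

// y (Co x Pp*N) = activation(conv3x3(x) + b), halo re-zeroed afterwards.
// slope = 0 gives ReLU, 1 gives the identity (linear output layer).
static void conv_s1(const fmat& x, int C, const fmat& W, const fvec& b,
                    int Co, const Grid& g, int N, float slope, fmat& y) {
  conv_core_taps(x, C, W, Co, g, N, y);
  y.each_col() += b;
  if (slope != 1.0f) lrelu_inplace(y, slope);
  zero_halo(y, Co, g, N);
}

// backward of conv_s1: dW, db and (optionally) dx; g must have zero halo
static void conv_s1_bwd(const fmat& g, const fmat& x, const fmat& W, int C,
                        int Co, const Grid& gr, int N, fmat& dW, fvec& db,
                        fmat* dx) {
  db = sum(g, 1);
  conv_dw_im2col(g, x, C, Co, gr, N, dW);
  if (dx) {
    // backward-input as a flipped-kernel forward conv of the gradient
    const fmat Wf = flip_weights(W, C, Co);
    conv_core_taps(g, Co, Wf, C, gr, N, *dx);
    zero_halo(*dx, C, gr, N);
  }
}

// --------------------------------- stride-2 conv: coarse-grid gather GEMM

// gather the 3x3 neighbourhoods of the stride-2 sample points of a fine
// halo map into cols (9C x Pp_coarse*N); coarse halo columns are zeroed so
// one GEMM covers the whole coarse padded grid
static void gather_s2(const fmat& x, int C, const Grid& fine,
                      const Grid& coarse, int N, fmat& cols) {
  const uword crows = 9 * (uword)C;
  cols.set_size(crows, coarse.Pp * (uword)N);
  const float* S = x.memptr();
  float* D = cols.memptr();
  const size_t cb = (size_t)C * sizeof(float);
  for (int n = 0; n < N; n++) {
    const float* sbase = S + (uword)n * fine.Pp * C;
    float* dbase = D + (uword)n * coarse.Pp * crows;
    std::memset(dbase, 0, (size_t)coarse.Hp * crows * sizeof(float));
    std::memset(dbase + (uword)(coarse.Wp - 1) * coarse.Hp * crows, 0,
                (size_t)coarse.Hp * crows * sizeof(float));
    for (int ox = 1; ox <= coarse.W; ox++) {
      float* dcol = dbase + (uword)ox * coarse.Hp * crows;
      std::memset(dcol, 0, crows * sizeof(float));
      std::memset(dcol + (uword)(coarse.Hp - 1) * crows, 0,
                  crows * sizeof(float));
      for (int dx = 0; dx < 3; dx++) {
        const int ix = 2 * ox + dx - 2;  // fine padded column
        for (int oy = 1; oy <= coarse.H; oy++) {
          // fine padded rows 2*oy-2 .. 2*oy: the three dy taps, contiguous
          std::memcpy(dcol + (uword)oy * crows + (uword)(dx * 3) * C,
                      sbase + ((uword)ix * fine.Hp + 2 * oy - 2) * C,
                      3 * cb);
        }
      }
    }
  }
}

// adjoint of gather_s2: scatter-add cols back onto the fine grid
static void scatter_s2(const fmat& cols, int C, const Grid& fine,
                       const Grid& coarse, int N, fmat& x) {
  const uword crows = 9 * (uword)C;
  x.zeros(C, fine.Pp * (uword)N);
  const float* S = cols.memptr();
  float* D = x.memptr();
  const int C3 = 3 * C;
  for (int n = 0; n < N; n++) {
    float* dbase = D + (uword)n * fine.Pp * C;
    const float* sbase = S + (uword)n * coarse.Pp * crows;
    for (int ox = 1; ox <= coarse.W; ox++) {
      const float* scol = sbase + (uword)ox * coarse.Hp * crows;
      for (int dx = 0; dx < 3; dx++) {
        const int ix = 2 * ox + dx - 2;
        for (int oy = 1; oy <= coarse.H; oy++) {
          float* d0 = dbase + ((uword)ix * fine.Hp + 2 * oy - 2) * C;
          const float* s0 = scol + (uword)oy * crows + (uword)(dx * 3) * C;
          for (int c = 0; c < C3; c++) d0[c] += s0[c];
        }
      }
    }
  }
}

struct PP {
  fmat W;
  fvec b;
};

static std::vector<PP> parse_params(Rcpp::List params) {
  std::vector<PP> pp(params.size());
  for (int i = 0; i < params.size(); i++) {
    Rcpp::List li = params[i];
    pp[i].W = to_f(Rcpp::as<Rcpp::NumericMatrix>(li["W"]));
    pp[i].b = to_fv(Rcpp::as<Rcpp::NumericVector>(li["b"]));
  }
  return pp;
}

// parameter ordering shared with the R constructor:
//   enc_a[1], enc_b[1], down[1], ..., enc_a[d], enc_b[d], down[d],
//   bot1, bot2, up[d], dec[d], ..., up[1], dec[1], out
static inline int idx_enc_a(int i) { return 3 * (i - 1); }
static inline int idx_enc_b(int i) { return 3 * (i - 1) + 1; }
static inline int idx_down(int i) { return 3 * (i - 1) + 2; }
static inline int idx_bot1(int d) { return 3 * d; }
static inline int idx_bot2(int d) { return 3 * d + 1; }
static inline int idx_up(int i, int d) { return 3 * d + 2 + 2 * (d - i); }
static inline int idx_dec(int i, int d) { return 3 * d + 3 + 2 * (d - i); }
static inline int idx_out(int d) { return 5 * d + 2; }

// persistent workspaces so large buffers survive across steps
struct Work {
  std::vector<fmat> colsD;  // gather cols of the down convs
  std::vector<fmat> aAct, sAct, dAct, uAct, decAct, catAct;
  fmat b1a, b2a, outAct;
  fmat x0;       // packed input batch
  fmat scratch;  // gather buffer shared by the up convs and backward
};
static Work wk;

// pack an (H, W, N) interior batch (one channel) into halo layout
static void pack_input(const float* src, const Grid& g, int N, fmat& dst) {
  dst.zeros(1, g.Pp * (uword)N);
  float* D = dst.memptr();
  for (int n = 0; n < N; n++)
    for (int x = 0; x < g.W; x++)
      std::memcpy(D + (uword)n * g.Pp + (uword)(x + 1) * g.Hp + 1,
                  src + (uword)n * g.H * g.W + (uword)x * g.H,
                  g.H * sizeof(float));
}

// extract the interior of a single-channel halo map into (H, W, N) order
static void unpack_output(const fmat& src, const Grid& g, int N, float* dst) {
  const float* S = src.memptr();
  for (int n = 0; n < N; n++)
    for (int x = 0; x < g.W; x++)
      std::memcpy(dst + (uword)n * g.H * g.W + (uword)x * g.H,
                  S + (uword)n * g.Pp + (uword)(x + 1) * g.Hp + 1,
                  g.H * sizeof(float));
}

// forward pass on the packed input in wk.x0; activations stay in `wk`
static const fmat& forward_pass(const std::vector<PP>& pp, int d,
                                const Rcpp::IntegerVector& channels,
                                const Grid& g0, int N, float slope) {
  wk.colsD.resize(d + 1);
  wk.aAct.resize(d + 1);
  wk.sAct.resize(d + 1);
  wk.dAct.resize(d + 1);
  wk.uAct.resize(d + 1);
  wk.decAct.resize(d + 1);
  wk.catAct.resize(d + 1);
  std::vector<Grid> grids(d + 2);
  grids[1] = g0;
  for (int i = 2; i <= d + 1; i++) grids[i] = grids[i - 1].half();

  const fmat* cur = &wk.x0;
  int cin = 1;
  for (int i = 1; i <= d; i++) {
    const Grid& gi = grids[i];
    const int ci = channels[i - 1];
    conv_s1(*cur, cin, pp[idx_enc_a(i)].W, pp[idx_enc_a(i)].b, ci, gi, N,
            slope, wk.aAct[i]);
    conv_s1(wk.aAct[i], ci, pp[idx_enc_b(i)].W, pp[idx_enc_b(i)].b, ci, gi,
            N, slope, wk.sAct[i]);
    const int cnext = (i < d) ? channels[i] : channels[d];
    gather_s2(wk.sAct[i], ci, gi, grids[i + 1], N, wk.colsD[i]);
    wk.dAct[i] = pp[idx_down(i)].W * wk.colsD[i];
    wk.dAct[i].each_col() += pp[idx_down(i)].b;
    lrelu_inplace(wk.dAct[i], slope);
    zero_halo(wk.dAct[i], cnext, grids[i + 1], N);
    cur = &wk.dAct[i];
    cin = cnext;
  }
  const Grid& gb = grids[d + 1];
  const int cb = channels[d];
  conv_s1(*cur, cb, pp[idx_bot1(d)].W, pp[idx_bot1(d)].b, cb, gb, N, slope,
          wk.b1a);
  conv_s1(wk.b1a, cb, pp[idx_bot2(d)].W, pp[idx_bot2(d)].b, cb, gb, N,
          slope, wk.b2a);
  cur = &wk.b2a;
  for (int i = d; i >= 1; i--) {
    const Grid& gi = grids[i];
    const int ci = channels[i - 1];
    // transposed conv: exact adjoint of the stride-2 conv level-i -> deeper
    wk.scratch = pp[idx_up(i, d)].W.t() * (*cur);
    scatter_s2(wk.scratch, ci, gi, grids[i + 1], N, wk.uAct[i]);
    wk.uAct[i].each_col() += pp[idx_up(i, d)].b;
    lrelu_inplace(wk.uAct[i], 0.0f);  // plain ReLU in the decoder
    zero_halo(wk.uAct[i], ci, gi, N);
    wk.catAct[i] = join_cols(wk.uAct[i], wk.sAct[i]);
    conv_s1(wk.catAct[i], 2 * ci, pp[idx_dec(i, d)].W, pp[idx_dec(i, d)].b,
            ci, gi, N, 0.0f, wk.decAct[i]);
    cur = &wk.decAct[i];
  }
  conv_s1(*cur, channels[0], pp[idx_out(d)].W, pp[idx_out(d)].b, 1, g0, N,
          1.0f, wk.outAct);
  return wk.outAct;
}

// composite training loss on the raw network output (halo layout):
//   l2   = sum m * (out - lab)^2             (m = mask, or 1 if unmasked)
//   amp  = squared detector-axis first-difference mismatch
//   diff = squared per-angle detector-sum mismatch
// writes the gradient of w_l2*l2 + w_amp*amp + w_diff*diff into gy
static void loss_and_grad(const fmat& y, const fmat& lab, const fmat& msk,
                          const Grid& g, int N, bool use_mask, float w_l2,
                          float w_amp, float w_diff, double* terms,
                          fmat& gy) {
  gy.zeros(1, y.n_cols);
  const float* Y = y.memptr();
  const float* L = lab.memptr();
  const float* M = msk.memptr();
  float* G = gy.memptr();
  const int H = g.H, W = g.W;
  double l2 = 0.0, amp = 0.0, dif = 0.0;
  std::vector<float> dcol(H);
  for (int n = 0; n < N; n++) {
    const uword off = (uword)n * g.Pp;
    for (int xw = 1; xw <= W; xw++) {
      const uword o = off + (uword)xw * g.Hp + 1;
      double csum = 0.0;
      for (int r = 0; r < H; r++) {
        const float dv = Y[o + r] - L[o + r];
        dcol[r] = dv;
        const float m = use_mask ? M[o + r] : 1.0f;
        l2 += (double)m * dv * dv;
        G[o + r] += w_l2 * 2.0f * m * dv;
        csum += dv;
      }
      for (int r = 0; r < H - 1; r++) {
        const float a = dcol[r + 1] - dcol[r];
        amp += (double)a * a;
        G[o + r] -= w_amp * 2.0f * a;
        G[o + r + 1] += w_amp * 2.0f * a;
      }
      dif += csum * csum;
      const float gd = w_diff * 2.0f * (float)csum;
      for (int r = 0; r < H; r++) G[o + r] += gd;
    }
  }
  terms[0] = l2;
  terms[1] = amp;
  terms[2] = dif;
}

// forward + loss + full backward for one packed batch; grads land in `gr`
static void compute_step(const std::vector<PP>& pp, const fmat& lb,
                         const fmat& mk, int d,
                         const Rcpp::IntegerVector& channels, const Grid& g0,
                         int N, float slope, float w_l2, float w_amp,
                         float w_diff, bool use_mask, double* terms,
                         std::vector<PP>& gr) {
  const fmat& y = forward_pass(pp, d, channels, g0, N, slope);

  std::vector<Grid> grids(d + 2);
  grids[1] = g0;
  for (int i = 2; i <= d + 1; i++) grids[i] = grids[i - 1].half();

  fmat g;
  loss_and_grad(y, lb, mk, g0, N, use_mask, w_l2, w_amp, w_diff, terms, g);

  std::vector<fmat> gskip(d + 1);
  fmat tmp;
  // output conv (input was decAct[1])
  conv_s1_bwd(g, wk.decAct[1], pp[idx_out(d)].W, channels[0], 1, g0, N,
              gr[idx_out(d)].W, gr[idx_out(d)].b, &tmp);
  g = tmp;
  // decoder, shallow -> deep
  for (int i = 1; i <= d; i++) {
    const Grid& gi = grids[i];
    const int ci = channels[i - 1];
    act_bwd(g, wk.decAct[i], 0.0f);
    fmat gcat;
    conv_s1_bwd(g, wk.catAct[i], pp[idx_dec(i, d)].W, 2 * ci, ci, gi, N,
                gr[idx_dec(i, d)].W, gr[idx_dec(i, d)].b, &gcat);
    fmat gu = gcat.rows(0, ci - 1);
    gskip[i] = gcat.rows(ci, 2 * ci - 1);
    act_bwd(gu, wk.uAct[i], 0.0f);
    gr[idx_up(i, d)].b = sum(gu, 1);
    gather_s2(gu, ci, gi, grids[i + 1], N, wk.scratch);
    const fmat& xin = (i == d) ? wk.b2a : wk.decAct[i + 1];
    gr[idx_up(i, d)].W = xin * wk.scratch.t();
    g = pp[idx_up(i, d)].W * wk.scratch;
    // g's halo is zero: gather_s2 zeroes the coarse halo columns
  }
  // bottleneck
  {
    const Grid& gb = grids[d + 1];
    const int cb = channels[d];
    act_bwd(g, wk.b2a, slope);
    conv_s1_bwd(g, wk.b1a, pp[idx_bot2(d)].W, cb, cb, gb, N,
                gr[idx_bot2(d)].W, gr[idx_bot2(d)].b, &tmp);
    g = tmp;
    act_bwd(g, wk.b1a, slope);
    conv_s1_bwd(g, wk.dAct[d], pp[idx_bot1(d)].W, cb, cb, gb, N,
                gr[idx_bot1(d)].W, gr[idx_bot1(d)].b, &tmp);
    g = tmp;
  }
  // encoder, deep -> shallow
  for (int i = d; i >= 1; i--) {
    const Grid& gi = grids[i];
    const int ci = channels[i - 1];
    act_bwd(g, wk.dAct[i], slope);
    gr[idx_down(i)].W = g * wk.colsD[i].t();
    gr[idx_down(i)].b = sum(g, 1);
    wk.scratch = pp[idx_down(i)].W.t() * g;
    scatter_s2(wk.scratch, ci, gi, grids[i + 1], N, tmp);
    zero_halo(tmp, ci, gi, N);  // drop gradients w.r.t. the zero padding
    g = tmp + gskip[i];
    act_bwd(g, wk.sAct[i], slope);
    conv_s1_bwd(g, wk.aAct[i], pp[idx_enc_b(i)].W, ci, ci, gi, N,
                gr[idx_enc_b(i)].W, gr[idx_enc_b(i)].b, &tmp);
    g = tmp;
    act_bwd(g, wk.aAct[i], slope);
    // input of enc_a(i): the previous down conv's output (or the image)
    conv_s1_bwd(g, (i > 1) ? wk.dAct[i - 1] : wk.x0, pp[idx_enc_a(i)].W,
                (i > 1) ? channels[i - 1] : 1, ci, gi, N,
                gr[idx_enc_a(i)].W, gr[idx_enc_a(i)].b,
                (i > 1) ? &tmp : (fmat*)0);
    if (i > 1) g = tmp;
  }
}

// [[Rcpp::export]]
Rcpp::List unet_step_cpp(Rcpp::List params, Rcpp::NumericVector x,
                         Rcpp::NumericVector lab, Rcpp::NumericVector mask,
                         Rcpp::IntegerVector dims, int depth,
                         Rcpp::IntegerVector channels, double slope,
                         double w_l2, double w_amp, double w_diff,
                         bool use_mask) {
  const int H = dims[0], W = dims[1], N = dims[2];
  const Grid g0(H, W);
  std::vector<PP> pp = parse_params(params);
  std::vector<float> buf(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) buf[i] = (float)x[i];
  pack_input(buf.data(), g0, N, wk.x0);
  fmat lb, mk;
  for (R_xlen_t i = 0; i < x.size(); i++) buf[i] = (float)lab[i];
  pack_input(buf.data(), g0, N, lb);
  for (R_xlen_t i = 0; i < x.size(); i++) buf[i] = (float)mask[i];
  pack_input(buf.data(), g0, N, mk);
  double terms[3];
  std::vector<PP> gr(pp.size());
  compute_step(pp, lb, mk, depth, channels, g0, N, (float)slope,
               (float)w_l2, (float)w_amp, (float)w_diff, use_mask, terms,
               gr);
  Rcpp::List grads(pp.size());
  for (size_t i = 0; i < gr.size(); i++)
    grads[i] = Rcpp::List::create(Rcpp::Named("W") = to_d(gr[i].W),
                                  Rcpp::Named("b") = to_dv(gr[i].b));
  return Rcpp::List::create(
      Rcpp::Named("l2") = terms[0], Rcpp::Named("amp") = terms[1],
      Rcpp::Named("diff") = terms[2],
      Rcpp::Named("total") =
          w_l2 * terms[0] + w_amp * terms[1] + w_diff * terms[2],
      Rcpp::Named("grads") = grads);
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_predict_cpp(Rcpp::List params,
                                     Rcpp::NumericVector x,
                                     Rcpp::IntegerVector dims, int depth,
                                     Rcpp::IntegerVector channels,
                                     double slope) {
  const int H = dims[0], W = dims[1], N = dims[2];
  const Grid g0(H, W);
  std::vector<PP> pp = parse_params(params);
  std::vector<float> buf(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) buf[i] = (float)x[i];
  pack_input(buf.data(), g0, N, wk.x0);
  const fmat& y = forward_pass(pp, depth, channels, g0, N, (float)slope);
  unpack_output(y, g0, N, buf.data());
  Rcpp::NumericVector res(x.size());
  for (R_xlen_t i = 0; i < res.size(); i++) res[i] = (double)buf[i];
  res.attr("dim") = dims;
  return res;
}

static inline void adam_update(float* P, float* M, float* V, const float* G,
                               uword n, float lr, float b1, float b2,
                               float eps, float c1, float c2) {
  for (uword i = 0; i < n; i++) {
    M[i] = b1 * M[i] + (1 - b1) * G[i];
    V[i] = b2 * V[i] + (1 - b2) * G[i] * G[i];
    P[i] -= lr * (M[i] / c1) / (std::sqrt(V[i] / c2) + eps);
  }
}

// full training loop: Adam on the composite loss with epoch-shuffled
// batches.  Shuffling draws from R's RNG, so a set.seed() on the R side
// makes the whole run reproducible.
// [[Rcpp::export]]
Rcpp::List unet_train_cpp(Rcpp::List params, Rcpp::NumericVector x_all,
                          Rcpp::NumericVector l_all,
                          Rcpp::NumericVector m_all,
                          Rcpp::IntegerVector dims, int depth,
                          Rcpp::IntegerVector channels, double slope,
                          double w_l2, double w_amp, double w_diff,
                          bool use_mask, int steps, int batch, double lr) {
  const int H = dims[0], W = dims[1], n_data = dims[2];
  const uword P = (uword)H * W;
  const Grid g0(H, W);
  std::vector<PP> pp = parse_params(params);
  std::vector<float> xa(x_all.size()), la(x_all.size()), ma(x_all.size());
  for (R_xlen_t i = 0; i < x_all.size(); i++) {
    xa[i] = (float)x_all[i];
    la[i] = (float)l_all[i];
    ma[i] = (float)m_all[i];
  }
  std::vector<PP> mom(pp.size()), vel(pp.size()), gr(pp.size());
  for (size_t k = 0; k < pp.size(); k++) {
    mom[k].W = zeros<fmat>(size(pp[k].W));
    mom[k].b = zeros<fvec>(pp[k].b.n_elem);
    vel[k].W = zeros<fmat>(size(pp[k].W));
    vel[k].b = zeros<fvec>(pp[k].b.n_elem);
  }
  Rcpp::NumericMatrix history(steps, 4);
  std::vector<float> xb(P * batch), lbv(P * batch), mbv(P * batch);
  fmat lb, mb;
  std::vector<int> pool;
  Rcpp::RNGScope rng;
  const float fb1 = 0.9f, fb2 = 0.999f, feps = 1e-8f;
  double terms[3];
  for (int step = 1; step <= steps; step++) {
    while ((int)pool.size() < batch) {
      std::vector<int> perm(n_data);
      for (int i = 0; i < n_data; i++) perm[i] = i;
      for (int i = n_data - 1; i > 0; i--) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      pool.insert(pool.end(), perm.begin(), perm.end());
    }
    for (int b = 0; b < batch; b++) {
      const uword src = (uword)pool[b] * P;
      std::memcpy(xb.data() + (uword)b * P, xa.data() + src,
                  P * sizeof(float));
      std::memcpy(lbv.data() + (uword)b * P, la.data() + src,
                  P * sizeof(float));
      std::memcpy(mbv.data() + (uword)b * P, ma.data() + src,
                  P * sizeof(float));
    }
    pool.erase(pool.begin(), pool.begin() + batch);
    pack_input(xb.data(), g0, batch, wk.x0);
    pack_input(lbv.data(), g0, batch, lb);
    pack_input(mbv.data(), g0, batch, mb);

    compute_step(pp, lb, mb, depth, channels, g0, batch, (float)slope,
                 (float)w_l2, (float)w_amp, (float)w_diff, use_mask, terms,
                 gr);
    const double total =
        w_l2 * terms[0] + w_amp * terms[1] + w_diff * terms[2];
    if (!std::isfinite(total))
      Rcpp::stop("training diverged at step %d (non-finite loss)", step);
    const float c1 = 1.0f - std::pow(fb1, (float)step);
    const float c2 = 1.0f - std::pow(fb2, (float)step);
    for (size_t k = 0; k < pp.size(); k++) {
      adam_update(pp[k].W.memptr(), mom[k].W.memptr(), vel[k].W.memptr(),
                  gr[k].W.memptr(), pp[k].W.n_elem, (float)lr, fb1, fb2,
                  feps, c1, c2);
      adam_update(pp[k].b.memptr(), mom[k].b.memptr(), vel[k].b.memptr(),
                  gr[k].b.memptr(), pp[k].b.n_elem, (float)lr, fb1, fb2,
                  feps, c1, c2);
    }
    history(step - 1, 0) = terms[0];
    history(step - 1, 1) = terms[1];
    history(step - 1, 2) = terms[2];
    history(step - 1, 3) = total;
    if (step % 50 == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::List out_params(pp.size());
  for (size_t k = 0; k < pp.size(); k++)
    out_params[k] = Rcpp::List::create(Rcpp::Named("W") = to_d(pp[k].W),
                                       Rcpp::Named("b") = to_dv(pp[k].b));
  return Rcpp::List::create(Rcpp::Named("params") = out_params,
                            Rcpp::Named("history") = history);
}
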