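// Native single-precision engine for the modified U-Net: GEMM-based (im2col)
// convolutions, strided downsampling convolutions, transpose-convolution
// upsampling implemented as the exact adjoint of a strided convolution,
// instance normalisation, leaky-ReLU, residual stages, skip concatenation,
// and the Dice + cross-entropy loss with full analytic backpropagation.
//
// Tensors are stored per sample as Armadillo fmat with rows = channels and
// columns = voxels in x-fastest order. im2col patch matrices use the
// channel-contiguous row layout k*C + c (kernel-offset major) so that patch
// extraction is a memcpy per kernel offset. All convolutions use kernel 3
// (1 along z in 2D mode), zero padding 1 ("same"), and the canonical
// parameter layout exposed by cpp_unet_layout() so that R and C++ agree on a
// single flat parameter vector. Patch matrices below a size threshold are
// cached between the forward and backward passes; larger ones are rebuilt in
// bounded-memory column chunks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cstring>
using namespace arma;

struct Shp {
  int nx, ny, nz;
  uword n() const { return (uword)nx * ny * nz; }
};

struct Blk {
  std::string name;
  int rows, cols;
  long off;
  double fan_in;
};

struct UCfg {
  int dims, in_ch, out_ch, L;
  std::vector<int> ch;
  float slope, eps;
  int kx, ky, kz, px, py, pz;
};

static UCfg parse_cfg(const Rcpp::List& cfg) {
  UCfg c;
  c.dims = Rcpp::as<int>(cfg["dims"]);
  c.in_ch = Rcpp::as<int>(cfg["in_channels"]);
  c.out_ch = Rcpp::as<int>(cfg["out_channels"]);
  c.ch = Rcpp::as<std::vector<int>>(cfg["channels"]);
  c.L = (int)c.ch.size();
  c.slope = (float)Rcpp::as<double>(cfg["slope"]);
  c.eps = (float)Rcpp::as<double>(cfg["eps"]);
  if (c.dims != 2 && c.dims != 3) Rcpp::stop("dims must be 2 or 3");
  if (c.L < 2) Rcpp::stop("at least two resolution levels are required");
  c.kx = 3; c.ky = 3; c.kz = (c.dims == 3) ? 3 : 1;
  c.px = 1; c.py = 1; c.pz = (c.dims == 3) ? 1 : 0;
  return c;
}

static std::vector<Blk> build_layout(const UCfg& c) {
  std::vector<Blk> b;
  long off = 0;
  const int K = c.kx * c.ky * c.kz;
  auto add = [&](const std::string& nm, int r, int cl, double fan) {
    b.push_back({nm, r, cl, off, fan});
    off += (long)r * cl;
  };
  auto add_conv = [&](const std::string& nm, int cin, int cout, int k, bool norm) {
    add(nm + "_W", cout, cin * k, (double)cin * k);
    add(nm + "_b", cout, 1, 0);
    if (norm) { add(nm + "_g", cout, 1, 0); add(nm + "_be", cout, 1, 0); }
  };
  for (int i = 0; i < c.L; ++i) {
    int cin = (i == 0) ? c.in_ch : c.ch[i - 1];
    add_conv("enc" + std::to_string(i) + "_down", cin, c.ch[i], K, true);
    add_conv("enc" + std::to_string(i) + "_res1", c.ch[i], c.ch[i], K, true);
    add_conv("enc" + std::to_string(i) + "_res2", c.ch[i], c.ch[i], K, true);
  }
  for (int j = c.L - 1; j >= 1; --j) {
    std::string nm = "dec" + std::to_string(j);
    // transpose conv stored as the adjoint convolution: (ch[j], ch[j-1]*K)
    add(nm + "_up_W", c.ch[j], c.ch[j - 1] * K, (double)c.ch[j] * K);
    add(nm + "_up_b", c.ch[j - 1], 1, 0);
    add(nm + "_up_g", c.ch[j - 1], 1, 0);
    add(nm + "_up_be", c.ch[j - 1], 1, 0);
    add_conv(nm + "_res1", 2 * c.ch[j - 1], c.ch[j - 1], K, true);
    add_conv(nm + "_res2", c.ch[j - 1], c.ch[j - 1], K, true);
    add(nm + "_proj_W", c.ch[j - 1], 2 * c.ch[j - 1], 2.0 * c.ch[j - 1]);
    add(nm + "_proj_b", c.ch[j - 1], 1, 0);
  }
  add("final_W", c.out_ch, c.ch[0], (double)c.ch[0]);
  add("final_b", c.out_ch, 1, 0);
  return b;
}

static long layout_total(const std::vector<Blk>& b) {
  if (b.empty()) return 0;
  const Blk& l = b.back();
  return l.off + (long)l.rows * l.cols;
}

// [[Rcpp::export]]
Rcpp::DataFrame cpp_unet_layout(Rcpp::List cfg) {
  UCfg c = parse_cfg(cfg);
  std::vector<Blk> b = build_layout(c);
  int n = (int)b.size();
  Rcpp::CharacterVector name(n);
  Rcpp::IntegerVector rows(n), cols(n);
  Rcpp::NumericVector off(n), len(n), fan(n);
  for (int i = 0; i < n; ++i) {
    name[i] = b[i].name; rows[i] = b[i].rows; cols[i] = b[i].cols;
    off[i] = (double)b[i].off + 1;  // 1-based for R
    len[i] = (double)b[i].rows * b[i].cols;
    fan[i] = b[i].fan_in;
  }
  return Rcpp::DataFrame::create(
    Rcpp::Named("block") = name, Rcpp::Named("rows") = rows,
    Rcpp::Named("cols") = cols, Rcpp::Named("offset") = off,
    Rcpp::Named("length") = len, Rcpp::Named("fan_in") = fan,
    Rcpp::Named("stringsAsFactors") = false);
}

// ---- low-level conv machinery -------------------------------------------

static const uword CACHE_MAX_ELEM = 12000000;  // floats; ~48 MB per patch matrix

static Shp conv_out_shape(const Shp& s, const UCfg& c, int st) {
  Shp o;
  o.nx = (s.nx + 2 * c.px - c.kx) / st + 1;
  o.ny = (s.ny + 2 * c.py - c.ky) / st + 1;
  o.nz = (c.dims == 3) ? (s.nz + 2 * c.pz - c.kz) / st + 1 : s.nz;
  return o;
}

// fill `col` (C*K x (c1-c0)) from X for output columns [c0, c1)
static void im2col_chunk(const fmat& X, const Shp& s, const UCfg& c, int st,
                         const Shp& o, uword c0, uword c1, fmat& col) {
  const int C = (int)X.n_rows;
  const int K = c.kx * c.ky * c.kz;
  const int stz = (c.dims == 3) ? st : 1;
  col.zeros(C * K, c1 - c0);
  const float* xp = X.memptr();
  for (uword oc = c0; oc < c1; ++oc) {
    uword t = oc;
    int ox = t % o.nx; t /= o.nx;
    int oy = t % o.ny;
    int oz = t / o.ny;
    int bx = ox * st - c.px, by = oy * st - c.py, bz = oz * stz - c.pz;
    float* dst = col.colptr(oc - c0);
    for (int iz = 0; iz < c.kz; ++iz) {
      int z = bz + iz; if (z < 0 || z >= s.nz) continue;
      for (int iy = 0; iy < c.ky; ++iy) {
        int y = by + iy; if (y < 0 || y >= s.ny) continue;
        uword vrow = (uword)s.nx * (y + (uword)s.ny * z);
        int kbase = c.kx * (iy + c.ky * iz);
        for (int ix = 0; ix < c.kx; ++ix) {
          int x = bx + ix; if (x < 0 || x >= s.nx) continue;
          std::memcpy(dst + (uword)(kbase + ix) * C,
                      xp + (x + vrow) * (uword)C, C * sizeof(float));
        }
      }
    }
  }
}

// scatter-add the adjoint of im2col_chunk
static void col2im_chunk(fmat& X, const Shp& s, const UCfg& c, int st,
                         const Shp& o, uword c0, uword c1, const fmat& col) {
  const int C = (int)X.n_rows;
  const int stz = (c.dims == 3) ? st : 1;
  float* xp = X.memptr();
  for (uword oc = c0; oc < c1; ++oc) {
    uword t = oc;
    int ox = t % o.nx; t /= o.nx;
    int oy = t % o.ny;
    int oz = t / o.ny;
    int bx = ox * st - c.px, by = oy * st - c.py, bz = oz * stz - c.pz;
    const float* src = col.colptr(oc - c0);
    for (int iz = 0; iz < c.kz; ++iz) {
      int z = bz + iz; if (z < 0 || z >= s.nz) continue;
      for (int iy = 0; iy < c.ky; ++iy) {
        int y = by + iy; if (y < 0 || y >= s.ny) continue;
        uword vrow = (uword)s.nx * (y + (uword)s.ny * z);
        int kbase = c.kx * (iy + c.ky * iz);
        for (int ix = 0; ix < c.kx; ++ix) {
          int x = bx + ix; if (x < 0 || x >= s.nx) continue;
          float* dst = xp + (x + vrow) * (uword)C;
          const float* sc = src + (uword)(kbase + ix) * C;
          for (int ci = 0; ci < C; ++ci) dst[ci] += sc[ci];
        }
      }
    }
  }
}

static uword chunk_cols(uword rows) {
  uword c = CACHE_MAX_ELEM / 2 / std::max((uword)1, rows);
  return std::max((uword)64, c);
}

struct ColCache { fmat col; bool valid = false; };

static void conv_fwd(const fmat& X, const Shp& s, const UCfg& c, int st,
                     const fmat& W, const fmat& b, fmat& Y, Shp& o,
                     ColCache* cache = nullptr) {
  o = conv_out_shape(s, c, st);
  Y.set_size(W.n_rows, o.n());
  if (cache && (uword)W.n_cols * o.n() <= CACHE_MAX_ELEM) {
    im2col_chunk(X, s, c, st, o, 0, o.n(), cache->col);
    cache->valid = true;
    Y = W * cache->col;
  } else {
    if (cache) cache->valid = false;
    fmat col;
    uword step = chunk_cols(W.n_cols);
    for (uword c0 = 0; c0 < o.n(); c0 += step) {
      uword c1 = std::min(c0 + step, o.n());
      im2col_chunk(X, s, c, st, o, c0, c1, col);
      Y.cols(c0, c1 - 1) = W * col;
    }
  }
  Y.each_col() += b.col(0);
}

static void conv_bwd(const fmat& X, const Shp& s, const UCfg& c, int st,
                     const fmat& W, const fmat& dY, const Shp& o,
                     fmat& dW, fmat& db, fmat& dX, const ColCache* cache = nullptr) {
  dX.zeros(X.n_rows, X.n_cols);
  if (cache && cache->valid) {
    dW += dY * cache->col.t();
    fmat dcol = W.t() * dY;
    col2im_chunk(dX, s, c, st, o, 0, o.n(), dcol);
  } else {
    fmat col;
    uword step = chunk_cols(W.n_cols);
    for (uword c0 = 0; c0 < o.n(); c0 += step) {
      uword c1 = std::min(c0 + step, o.n());
      im2col_chunk(X, s, c, st, o, c0, c1, col);
      dW += dY.cols(c0, c1 - 1) * col.t();
      fmat dcol = W.t() * dY.cols(c0, c1 - 1);
      col2im_chunk(dX, s, c, st, o, c0, c1, dcol);
    }
  }
  db.col(0) += sum(dY, 1);
}

// transpose convolution: the exact adjoint of conv(stride 2) from `o` to `si`.
// Wt has shape (cin, cout*K); input X lives on the small grid si, output on o.
static void tconv_fwd(const fmat& X, const Shp& si, const UCfg& c,
                      const fmat& Wt, const fmat& b, fmat& Y, const Shp& o) {
  Y.zeros(Wt.n_cols / (c.kx * c.ky * c.kz), o.n());
  uword step = chunk_cols(Wt.n_cols);
  for (uword c0 = 0; c0 < si.n(); c0 += step) {
    uword c1 = std::min(c0 + step, si.n());
    fmat dcol = Wt.t() * X.cols(c0, c1 - 1);
    col2im_chunk(Y, o, c, 2, si, c0, c1, dcol);
  }
  Y.each_col() += b.col(0);
}

static void tconv_bwd(const fmat& X, const Shp& si, const UCfg& c,
                      const fmat& Wt, const fmat& dY, const Shp& o,
                      fmat& dWt, fmat& db, fmat& dX) {
  dX.set_size(X.n_rows, X.n_cols);
  fmat col;
  uword step = chunk_cols(Wt.n_cols);
  for (uword c0 = 0; c0 < si.n(); c0 += step) {
    uword c1 = std::min(c0 + step, si.n());
    im2col_chunk(dY, o, c, 2, si, c0, c1, col);
    dX.cols(c0, c1 - 1) = Wt * col;
    dWt += X.cols(c0, c1 - 1) * col.t();
  }
  db.col(0) += sum(dY, 1);
}

// instance norm forward; stores xhat and per-channel 1/sd for backward
static void in_fwd(const fmat& A, const fmat& g, const fmat& be, float eps,
                   fmat& Y, fmat& xhat, fvec& istd) {
  const uword C = A.n_rows, N = A.n_cols;
  xhat.set_size(C, N); Y.set_size(C, N); istd.set_size(C);
  std::vector<double> m(C, 0.0), v(C, 0.0);
  const float* a = A.memptr();
  for (uword col = 0; col < N; ++col) {
    const float* ac = a + col * C;
    for (uword c = 0; c < C; ++c) m[c] += ac[c];
  }
  for (uword c = 0; c < C; ++c) m[c] /= N;
  for (uword col = 0; col < N; ++col) {
    const float* ac = a + col * C;
    for (uword c = 0; c < C; ++c) { double d = ac[c] - m[c]; v[c] += d * d; }
  }
  std::vector<float> mf(C), gf(C), bf(C);
  for (uword c = 0; c < C; ++c) {
    istd(c) = (float)(1.0 / std::sqrt(v[c] / N + eps));
    mf[c] = (float)m[c]; gf[c] = g(c, 0); bf[c] = be(c, 0);
  }
  float* xh = xhat.memptr();
  float* y = Y.memptr();
  for (uword col = 0; col < N; ++col) {
    const float* ac = a + col * C;
    float* xc = xh + col * C;
    float* yc = y + col * C;
    for (uword c = 0; c < C; ++c) {
      xc[c] = (ac[c] - mf[c]) * istd(c);
      yc[c] = gf[c] * xc[c] + bf[c];
    }
  }
}

static void in_bwd(const fmat& dY, const fmat& xhat, const fvec& istd,
                   const fmat& g, fmat& dg, fmat& dbe, fmat& dA) {
  const uword C = dY.n_rows, N = dY.n_cols;
  dA.set_size(C, N);
  std::vector<double> sdg(C, 0.0), sdb(C, 0.0);
  const float* dy = dY.memptr();
  const float* xh = xhat.memptr();
  for (uword col = 0; col < N; ++col) {
    const float* dc = dy + col * C;
    const float* xc = xh + col * C;
    for (uword c = 0; c < C; ++c) { sdg[c] += (double)dc[c] * xc[c]; sdb[c] += dc[c]; }
  }
  std::vector<float> gm(C), mdxh(C), mdxhx(C);
  for (uword c = 0; c < C; ++c) {
    dg(c, 0) += (float)sdg[c];
    dbe(c, 0) += (float)sdb[c];
    gm[c] = g(c, 0);
    mdxh[c] = (float)(gm[c] * sdb[c] / N);
    mdxhx[c] = (float)(gm[c] * sdg[c] / N);
  }
  float* da = dA.memptr();
  for (uword col = 0; col < N; ++col) {
    const float* dc = dy + col * C;
    const float* xc = xh + col * C;
    float* dac = da + col * C;
    for (uword c = 0; c < C; ++c)
      dac[c] = istd(c) * (gm[c] * dc[c] - mdxh[c] - xc[c] * mdxhx[c]);
  }
}

static inline void act_fwd(fmat& A, float slope) {
  float* a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] < 0) a[i] *= slope;
}

static inline fmat act_bwd(const fmat& dY, const fmat& Yact, float slope) {
  fmat m = dY;
  const uword n = m.n_elem;
  const float* y = Yact.memptr();
  float* d = m.memptr();
  for (uword i = 0; i < n; ++i) if (y[i] <= 0) d[i] *= slope;
  return m;
}

// ---- parameter access ----------------------------------------------------

struct Params {
  const std::vector<Blk>* lay;
  fvec* vec;
  std::map<std::string, int> idx;
  Params(const std::vector<Blk>& l, fvec& v) : lay(&l), vec(&v) {
    for (int i = 0; i < (int)l.size(); ++i) idx[l[i].name] = i;
  }
  fmat view(const std::string& nm) {
    auto it = idx.find(nm);
    if (it == idx.end()) Rcpp::stop("unknown parameter block: " + nm);
    const Blk& b = (*lay)[it->second];
    return fmat(vec->memptr() + b.off, b.rows, b.cols, false, true);
  }
};

// ---- caches ---------------------------------------------------------------

struct NormCache { fmat xhat; fvec istd; fmat actout; };
struct StageCache {
  fmat in;
  NormCache n1, n2;
  ColCache col1, col2;
  bool proj;
};
struct DownCache { fmat in; Shp si, so; NormCache n; ColCache col; };
struct UpCache { fmat in; Shp si, so; NormCache n; };

struct NetCache {
  std::vector<fmat> enc_out;
  std::vector<Shp> enc_shp;
  std::vector<DownCache> down;
  std::vector<StageCache> enc_res;
  std::vector<UpCache> up;
  std::vector<StageCache> dec_res;
  fmat top;
  Shp top_shp;
};

// residual stage: out = shortcut(in) + act(IN2(conv2(act(IN1(conv1(in))))))
static fmat stage_fwd(const fmat& X, const Shp& s, const UCfg& c, Params& P,
                      const std::string& nm, bool proj, StageCache& sc) {
  sc.in = X; sc.proj = proj;
  Shp o;
  fmat a1;
  conv_fwd(X, s, c, 1, P.view(nm + "_res1_W"), P.view(nm + "_res1_b"), a1, o, &sc.col1);
  fmat h1;
  in_fwd(a1, P.view(nm + "_res1_g"), P.view(nm + "_res1_be"), c.eps, h1, sc.n1.xhat, sc.n1.istd);
  act_fwd(h1, c.slope);
  sc.n1.actout = h1;
  fmat a2;
  conv_fwd(h1, s, c, 1, P.view(nm + "_res2_W"), P.view(nm + "_res2_b"), a2, o, &sc.col2);
  fmat h2;
  in_fwd(a2, P.view(nm + "_res2_g"), P.view(nm + "_res2_be"), c.eps, h2, sc.n2.xhat, sc.n2.istd);
  act_fwd(h2, c.slope);
  sc.n2.actout = h2;
  fmat out;
  if (proj) {
    out = P.view(nm + "_proj_W") * X;
    out.each_col() += P.view(nm + "_proj_b").col(0);
    out += h2;
  } else {
    out = X + h2;
  }
  return out;
}

static fmat stage_bwd(const fmat& dOut, const Shp& s, const UCfg& c, Params& P,
                      Params& G, const std::string& nm, const StageCache& sc) {
  fmat dh2 = act_bwd(dOut, sc.n2.actout, c.slope);
  fmat da2;
  {
    fmat dg = G.view(nm + "_res2_g"), dbe = G.view(nm + "_res2_be");
    in_bwd(dh2, sc.n2.xhat, sc.n2.istd, P.view(nm + "_res2_g"), dg, dbe, da2);
  }
  fmat dz1;
  {
    fmat dW = G.view(nm + "_res2_W"), db = G.view(nm + "_res2_b");
    conv_bwd(sc.n1.actout, s, c, 1, P.view(nm + "_res2_W"), da2, s, dW, db, dz1, &sc.col2);
  }
  fmat dh1 = act_bwd(dz1, sc.n1.actout, c.slope);
  fmat da1;
  {
    fmat dg = G.view(nm + "_res1_g"), dbe = G.view(nm + "_res1_be");
    in_bwd(dh1, sc.n1.xhat, sc.n1.istd, P.view(nm + "_res1_g"), dg, dbe, da1);
  }
  fmat dX;
  {
    fmat dW = G.view(nm + "_res1_W"), db = G.view(nm + "_res1_b");
    conv_bwd(sc.in, s, c, 1, P.view(nm + "_res1_W"), da1, s, dW, db, dX, &sc.col1);
  }
  if (sc.proj) {
    fmat dWp = G.view(nm + "_proj_W");
    dWp += dOut * sc.in.t();
    G.view(nm + "_proj_b").col(0) += sum(dOut, 1);
    dX += P.view(nm + "_proj_W").t() * dOut;
  } else {
    dX += dOut;
  }
  return dX;
}

static void check_divisible(const UCfg& c, const Shp& s) {
  int m = 1 << (c.L - 1);
  if (s.nx % m != 0) Rcpp::stop("input x extent (%d) not divisible by %d", s.nx, m);
  if (s.ny % m != 0) Rcpp::stop("input y extent (%d) not divisible by %d", s.ny, m);
  if (c.dims == 3 && s.nz % m != 0)
    Rcpp::stop("input z extent (%d) not divisible by %d", s.nz, m);
  if (c.dims == 2 && s.nz != 1) Rcpp::stop("2D networks take single-slice input (nz = 1)");
}

static fmat net_fwd(const fmat& X0, const Shp& s0, const UCfg& c, Params& P,
                    NetCache& nc) {
  check_divisible(c, s0);
  nc.enc_out.resize(c.L); nc.enc_shp.resize(c.L);
  nc.down.resize(c.L); nc.enc_res.resize(c.L);
  nc.up.resize(c.L); nc.dec_res.resize(c.L);
  fmat x = X0;
  Shp s = s0;
  for (int i = 0; i < c.L; ++i) {
    std::string nm = "enc" + std::to_string(i);
    int st = (i == 0) ? 1 : 2;
    DownCache& dc = nc.down[i];
    dc.in = x; dc.si = s;
    fmat a;
    Shp o;
    conv_fwd(x, s, c, st, P.view(nm + "_down_W"), P.view(nm + "_down_b"), a, o, &dc.col);
    dc.so = o;
    fmat h;
    in_fwd(a, P.view(nm + "_down_g"), P.view(nm + "_down_be"), c.eps, h,
           dc.n.xhat, dc.n.istd);
    act_fwd(h, c.slope);
    dc.n.actout = h;
    s = o;
    x = stage_fwd(h, s, c, P, nm, false, nc.enc_res[i]);
    nc.enc_out[i] = x;
    nc.enc_shp[i] = s;
  }
  for (int j = c.L - 1; j >= 1; --j) {
    std::string nm = "dec" + std::to_string(j);
    Shp so = nc.enc_shp[j - 1];
    UpCache& uc = nc.up[j];
    uc.in = x; uc.si = s; uc.so = so;
    fmat a;
    tconv_fwd(x, s, c, P.view(nm + "_up_W"), P.view(nm + "_up_b"), a, so);
    fmat h;
    in_fwd(a, P.view(nm + "_up_g"), P.view(nm + "_up_be"), c.eps, h,
           uc.n.xhat, uc.n.istd);
    act_fwd(h, c.slope);
    uc.n.actout = h;
    fmat cat = join_cols(h, nc.enc_out[j - 1]);  // upsampled first, then skip
    s = so;
    x = stage_fwd(cat, s, c, P, nm, true, nc.dec_res[j]);
  }
  nc.top = x; nc.top_shp = s;
  fmat scores = P.view("final_W") * x;
  scores.each_col() += P.view("final_b").col(0);
  return scores;
}

static void net_bwd(const fmat& dScores, const UCfg& c, Params& P, Params& G,
                    NetCache& nc) {
  {
    fmat dW = G.view("final_W");
    dW += dScores * nc.top.t();
    G.view("final_b").col(0) += sum(dScores, 1);
  }
  fmat dx = P.view("final_W").t() * dScores;
  std::vector<fmat> dskip(c.L);
  // decoder backward, reverse of forward order (last forward step was j = 1)
  for (int j = 1; j <= c.L - 1; ++j) {
    std::string nm = "dec" + std::to_string(j);
    fmat dcat = stage_bwd(dx, nc.enc_shp[j - 1], c, P, G, nm, nc.dec_res[j]);
    int cup = c.ch[j - 1];
    fmat dh = dcat.rows(0, cup - 1);
    dskip[j - 1] = dcat.rows(cup, dcat.n_rows - 1);
    fmat dhh = act_bwd(dh, nc.up[j].n.actout, c.slope);
    fmat da;
    {
      fmat dg = G.view(nm + "_up_g"), dbe = G.view(nm + "_up_be");
      in_bwd(dhh, nc.up[j].n.xhat, nc.up[j].n.istd, P.view(nm + "_up_g"), dg, dbe, da);
    }
    fmat dWt = G.view(nm + "_up_W"), db = G.view(nm + "_up_b");
    fmat dxn;
    tconv_bwd(nc.up[j].in, nc.up[j].si, c, P.view(nm + "_up_W"), da,
              nc.up[j].so, dWt, db, dxn);
    dx = dxn;
  }
  // encoder backward: dx is the gradient at enc_out[L-1]
  for (int i = c.L - 1; i >= 0; --i) {
    std::string nm = "enc" + std::to_string(i);
    if (dskip[i].n_elem) dx += dskip[i];
    fmat dh = stage_bwd(dx, nc.enc_shp[i], c, P, G, nm, nc.enc_res[i]);
    fmat dhh = act_bwd(dh, nc.down[i].n.actout, c.slope);
    fmat da;
    {
      fmat dg = G.view(nm + "_down_g"), dbe = G.view(nm + "_down_be");
      in_bwd(dhh, nc.down[i].n.xhat, nc.down[i].n.istd, P.view(nm + "_down_g"),
             dg, dbe, da);
    }
    int st = (i == 0) ? 1 : 2;
    fmat dWc = G.view(nm + "_down_W"), dbc = G.view(nm + "_down_b");
    fmat dxn;
    conv_bwd(nc.down[i].in, nc.down[i].si, c, st, P.view(nm + "_down_W"), da,
             nc.down[i].so, dWc, dbc, dxn, &nc.down[i].col);
    dx = dxn;
  }
}

// ---- loss -----------------------------------------------------------------

// softmax + soft Dice (smoothing in numerator and denominator) + voxel-mean
// cross entropy on one sample. scores: (C, N); labels in 0..C-1.
static void dice_ce_sample(const fmat& S, const Rcpp::IntegerVector& lab,
                           uword lab_off, float smooth,
                           double& dice_loss, double& ce_loss, fmat& dS) {
  const uword C = S.n_rows, N = S.n_cols;
  fmat Pm(C, N);
  const float* sp = S.memptr();
  float* pp = Pm.memptr();
  double ce = 0;
  for (uword v = 0; v < N; ++v) {
    const float* sc = sp + v * C;
    float* pc = pp + v * C;
    float mx = sc[0];
    for (uword c = 1; c < C; ++c) mx = std::max(mx, sc[c]);
    double tot = 0;
    for (uword c = 0; c < C; ++c) { pc[c] = std::exp(sc[c] - mx); tot += pc[c]; }
    float inv = (float)(1.0 / tot);
    for (uword c = 0; c < C; ++c) pc[c] *= inv;
    ce -= std::log(std::max((double)pc[lab[lab_off + v]], 1e-12));
  }
  ce /= (double)N;
  std::vector<double> inter(C, 0.0), psum(C, 0.0), tsum(C, 0.0);
  for (uword v = 0; v < N; ++v) {
    const float* pc = pp + v * C;
    for (uword c = 0; c < C; ++c) psum[c] += pc[c];
    int l = lab[lab_off + v];
    tsum[l] += 1.0;
    inter[l] += pc[l];
  }
  double dsum = 0;
  std::vector<float> den(C), num(C);
  for (uword c = 0; c < C; ++c) {
    den[c] = (float)(psum[c] + tsum[c] + smooth);
    num[c] = (float)(2.0 * inter[c] + smooth);
    dsum += num[c] / den[c];
  }
  dice_loss = 1.0 - dsum / (double)C;
  ce_loss = ce;
  // dL/dP for the dice part, then chain through softmax; CE added on scores
  dS.set_size(C, N);
  float* ds = dS.memptr();
  const float invN = 1.0f / (float)N;
  const float invC = 1.0f / (float)C;
  std::vector<float> gp(C);
  for (uword v = 0; v < N; ++v) {
    const float* pc = pp + v * C;
    float* dc = ds + v * C;
    int l = lab[lab_off + v];
    float dot = 0;
    for (uword c = 0; c < C; ++c) {
      float t = (l == (int)c) ? 1.0f : 0.0f;
      gp[c] = -invC * (2.0f * t * den[c] - num[c]) / (den[c] * den[c]);
      dot += gp[c] * pc[c];
    }
    for (uword c = 0; c < C; ++c)
      dc[c] = pc[c] * (gp[c] - dot) + invN * pc[c];
    dc[l] -= invN;
  }
}

// ---- R entry points -------------------------------------------------------

static void sample_to_fmat(const double* x, uword N, int C, uword samp, fmat& X) {
  X.set_size(C, N);
  float* dst = X.memptr();
  for (int c = 0; c < C; ++c) {
    const double* src = x + N * (c + (uword)C * samp);
    for (uword v = 0; v < N; ++v) dst[c + (uword)C * v] = (float)src[v];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_unet_forward(Rcpp::List cfg, Rcpp::NumericVector params,
                                     Rcpp::NumericVector x) {
  UCfg c = parse_cfg(cfg);
  std::vector<Blk> lay = build_layout(c);
  long tot = layout_total(lay);
  if ((long)params.size() != tot)
    Rcpp::stop("parameter vector has length %d, expected %d", (int)params.size(), (int)tot);
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 5) Rcpp::stop("input must be a 5D array (nx, ny, nz, channels, batch)");
  Shp s{d[0], d[1], d[2]};
  int cin = d[3], nb = d[4];
  if (cin != c.in_ch) Rcpp::stop("input has %d channels, expected %d", cin, c.in_ch);
  fvec P = conv_to<fvec>::from(Rcpp::as<arma::vec>(params));
  Params PP(lay, P);
  Rcpp::NumericVector out((R_xlen_t)s.n() * c.out_ch * nb);
  for (int b = 0; b < nb; ++b) {
    fmat X;
    sample_to_fmat(x.begin(), s.n(), cin, b, X);
    NetCache nc;
    fmat S = net_fwd(X, s, c, PP, nc);
    for (int ch = 0; ch < c.out_ch; ++ch) {
      double* dst = out.begin() + s.n() * (ch + (uword)c.out_ch * b);
      for (uword v = 0; v < s.n(); ++v) dst[v] = (double)S(ch, v);
    }
  }
  out.attr("dim") = Rcpp::IntegerVector::create(d[0], d[1], d[2], c.out_ch, nb);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_loss_grad(Rcpp::List cfg, Rcpp::NumericVector params,
                              Rcpp::NumericVector x, Rcpp::IntegerVector labels,
                              double smooth) {
  UCfg c = parse_cfg(cfg);
  std::vector<Blk> lay = build_layout(c);
  long tot = layout_total(lay);
  if ((long)params.size() != tot) Rcpp::stop("parameter vector length mismatch");
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 5) Rcpp::stop("input must be a 5D array");
  Shp s{d[0], d[1], d[2]};
  int cin = d[3], nb = d[4];
  if ((uword)labels.size() != s.n() * (uword)nb) Rcpp::stop("label array size mismatch");
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] < 0 || labels[i] >= c.out_ch) Rcpp::stop("label outside 0..%d", c.out_ch - 1);
  fvec P = conv_to<fvec>::from(Rcpp::as<arma::vec>(params));
  fvec G(tot, fill::zeros);
  Params PP(lay, P), GG(lay, G);
  double dice_tot = 0, ce_tot = 0;
  for (int b = 0; b < nb; ++b) {
    fmat X;
    sample_to_fmat(x.begin(), s.n(), cin, b, X);
    NetCache nc;
    fmat S = net_fwd(X, s, c, PP, nc);
    double dl, cl;
    fmat dS;
    dice_ce_sample(S, labels, s.n() * (uword)b, (float)smooth, dl, cl, dS);
    dice_tot += dl; ce_tot += cl;
    dS /= (float)nb;
    net_bwd(dS, c, PP, GG, nc);
  }
  dice_tot /= nb; ce_tot /= nb;
  Rcpp::NumericVector grad(tot);
  for (long i = 0; i < tot; ++i) grad[i] = (double)G(i);
  return Rcpp::List::create(
    Rcpp::Named("loss") = dice_tot + ce_tot,
    Rcpp::Named("dice_loss") = dice_tot,
    Rcpp::Named("ce_loss") = ce_tot,
    Rcpp::Named("grad") = grad);
}

// standalone DiceCE evaluation (user-facing loss function)
// [[Rcpp::export]]
Rcpp::List cpp_dice_ce(Rcpp::NumericMatrix scores, Rcpp::IntegerVector labels,
                       double smooth) {
  fmat S(scores.nrow(), scores.ncol());
  for (int i = 0; i < scores.nrow(); ++i)
    for (int j = 0; j < scores.ncol(); ++j) S(i, j) = (float)scores(i, j);
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] < 0 || labels[i] >= scores.nrow()) Rcpp::stop("label out of range");
  if ((int)labels.size() != scores.ncol()) Rcpp::stop("labels must match score columns");
  double dl, cl;
  fmat dS;
  dice_ce_sample(S, labels, 0, (float)smooth, dl, cl, dS);
  Rcpp::NumericMatrix g(scores.nrow(), scores.ncol());
  for (int i = 0; i < g.nrow(); ++i)
    for (int j = 0; j < g.ncol(); ++j) g(i, j) = (double)dS(i, j);
  return Rcpp::List::create(
    Rcpp::Named("loss") = dl + cl, Rcpp::Named("dice_loss") = dl,
    Rcpp::Named("ce_loss") = cl, Rcpp::Named("grad") = g);
}

// ---- small exported building blocks (used by the test-suite oracles) ------

// generic strided 3D convolution; w is (cout, cin*K) in the engine layout:
// column index = k*cin + c with k = ix + kx*(iy + ky*iz).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv3d(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                               Rcpp::NumericVector bias, int stride, int dims) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("input must be (nx, ny, nz, channels)");
  UCfg c;
  c.dims = dims; c.kx = 3; c.ky = 3; c.kz = dims == 3 ? 3 : 1;
  c.px = 1; c.py = 1; c.pz = dims == 3 ? 1 : 0;
  Shp s{d[0], d[1], d[2]};
  int cin = d[3];
  if ((int)w.ncol() != cin * c.kx * c.ky * c.kz) Rcpp::stop("weight shape mismatch");
  fmat X;
  sample_to_fmat(x.begin(), s.n(), cin, 0, X);
  fmat W(w.nrow(), w.ncol());
  for (int i = 0; i < w.nrow(); ++i)
    for (int j = 0; j < w.ncol(); ++j) W(i, j) = (float)w(i, j);
  fmat B(w.nrow(), 1);
  for (int i = 0; i < w.nrow(); ++i) B(i, 0) = (float)bias[i];
  fmat Y;
  Shp o;
  conv_fwd(X, s, c, stride, W, B, Y, o);
  Rcpp::NumericVector out((R_xlen_t)o.n() * w.nrow());
  for (int ch = 0; ch < w.nrow(); ++ch)
    for (uword v = 0; v < o.n(); ++v)
      out[v + o.n() * ch] = (double)Y(ch, v);
  out.attr("dim") = Rcpp::IntegerVector::create(o.nx, o.ny, o.nz, w.nrow());
  return out;
}

// transpose convolution (stride 2), the exact adjoint of cpp_conv3d's
// stride-2 map; wt is (cin, cout*K); output doubles each convolved axis.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_tconv3d(Rcpp::NumericVector x, Rcpp::NumericMatrix wt,
                                Rcpp::NumericVector bias, int dims) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("input must be (nx, ny, nz, channels)");
  UCfg c;
  c.dims = dims; c.kx = 3; c.ky = 3; c.kz = dims == 3 ? 3 : 1;
  c.px = 1; c.py = 1; c.pz = dims == 3 ? 1 : 0;
  Shp s{d[0], d[1], d[2]};
  int cin = d[3];
  int K = c.kx * c.ky * c.kz;
  if ((int)wt.nrow() != cin) Rcpp::stop("weight rows must equal input channels");
  int cout = wt.ncol() / K;
  Shp o{s.nx * 2, s.ny * 2, dims == 3 ? s.nz * 2 : s.nz};
  fmat X;
  sample_to_fmat(x.begin(), s.n(), cin, 0, X);
  fmat W(wt.nrow(), wt.ncol());
  for (int i = 0; i < wt.nrow(); ++i)
    for (int j = 0; j < wt.ncol(); ++j) W(i, j) = (float)wt(i, j);
  fmat B(cout, 1);
  for (int i = 0; i < cout; ++i) B(i, 0) = (float)bias[i];
  fmat Y;
  tconv_fwd(X, s, c, W, B, Y, o);
  Rcpp::NumericVector out((R_xlen_t)o.n() * cout);
  for (int ch = 0; ch < cout; ++ch)
    for (uword v = 0; v < o.n(); ++v)
      out[v + o.n() * ch] = (double)Y(ch, v);
  out.attr("dim") = Rcpp::IntegerVector::create(o.nx, o.ny, o.nz, cout);
  return out;
}

// instance normalisation on a (channels x voxels) matrix
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_instance_norm(Rcpp::NumericMatrix x, Rcpp::NumericVector gamma,
                                      Rcpp::NumericVector beta, double eps) {
  fmat X(x.nrow(), x.ncol());
  for (int i = 0; i < x.nrow(); ++i)
    for (int j = 0; j < x.ncol(); ++j) X(i, j) = (float)x(i, j);
  fmat g(x.nrow(), 1), be(x.nrow(), 1);
  for (int i = 0; i < x.nrow(); ++i) { g(i, 0) = (float)gamma[i]; be(i, 0) = (float)beta[i]; }
  fmat Y, xhat;
  fvec istd;
  in_fwd(X, g, be, (float)eps, Y, xhat, istd);
  Rcpp::NumericMatrix out(x.nrow(), x.ncol());
  for (int i = 0; i < x.nrow(); ++i)
    for (int j = 0; j < x.ncol(); ++j) out(i, j) = (double)Y(i, j);
  return out;
}

// named intermediate activations for one sample (architecture introspection)
// [[Rcpp::export]]
Rcpp::List cpp_unet_activations(Rcpp::List cfg, Rcpp::NumericVector params,
                                Rcpp::NumericVector x) {
  UCfg c = parse_cfg(cfg);
  std::vector<Blk> lay = build_layout(c);
  if ((long)params.size() != layout_total(lay)) Rcpp::stop("parameter vector length mismatch");
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("input must be (nx, ny, nz, channels)");
  Shp s{d[0], d[1], d[2]};
  fvec P = conv_to<fvec>::from(Rcpp::as<arma::vec>(params));
  Params PP(lay, P);
  fmat X;
  sample_to_fmat(x.begin(), s.n(), d[3], 0, X);
  NetCache nc;
  fmat S = net_fwd(X, s, c, PP, nc);
  auto tomat = [](const fmat& M) {
    Rcpp::NumericMatrix out(M.n_rows, M.n_cols);
    for (uword i = 0; i < M.n_rows; ++i)
      for (uword j = 0; j < M.n_cols; ++j) out(i, j) = (double)M(i, j);
    return out;
  };
  Rcpp::List res;
  for (int i = 0; i < c.L; ++i) {
    res["enc" + std::to_string(i) + "_down"] = tomat(nc.down[i].n.actout);
    res["enc" + std::to_string(i) + "_res"] = tomat(nc.enc_out[i]);
  }
  res["scores"] = tomat(S);
  return res;
}
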