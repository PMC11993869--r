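// Whole-network forward/backward for the circular-padded attention U-Net,
// single precision end to end.  The layer semantics are identical to the
// R composition in R/model.R (which the tests keep as an independent
// reference); this path exists so training does not pay R<->C conversion
// costs per layer.  The forward cache lives in an external pointer and is
// consumed by the matching backward call.

#include <RcppArmadillo.h>
#include <map>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

struct Lvl {
  int H, W;
};

struct ConvBlk {
  fmat a, xhat;
  fvec s;
};

struct Cache {
  int D = 0, base = 0, pad_mode = 0, attention = 1;
  int H0 = 0, W0 = 0;
  std::vector<Lvl> lvl;                     // level dims, index 0..D (D = bottleneck)
  std::vector<fmat> enc_in;                 // input to enc block i
  std::vector<ConvBlk> enc1, enc2;          // per level
  std::vector<arma::uvec> pool_idx;
  ConvBlk bot1, bot2;
  fmat bot_in;
  std::vector<fmat> u0, u;                  // decoder upsample / projected
  std::vector<fmat> att_q;
  std::vector<fvec> att_alpha;
  std::vector<fmat> cat;
  std::vector<ConvBlk> dec1, dec2;
  fmat head_in;
  fvec prob;
};

typedef std::map<std::string, NumericVector> ParamMap;

fmat get_w(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  SEXP dimsexp = v.attr("dim");
  fmat out;
  if (Rf_isNull(dimsexp)) {
    out.set_size(v.size(), 1);
  } else {
    IntegerVector d(dimsexp);
    if (d.size() == 4) out.set_size((uword)d[0] * d[1] * d[2], d[3]);
    else if (d.size() == 2) out.set_size(d[0], d[1]);
    else out.set_size(v.size(), 1);
  }
  const double* src = v.begin();
  float* dst = out.memptr();
  for (uword i = 0; i < out.n_elem; ++i) dst[i] = (float)src[i];
  return out;
}

fvec get_v(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

NumericVector put_arr(const fmat& m, SEXP like) {
  NumericVector v(m.n_elem);
  const float* src = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i) v[i] = src[i];
  NumericVector ref(like);
  v.attr("dim") = ref.attr("dim");
  return v;
}

NumericVector put_vec(const fvec& x) {
  NumericVector v(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) v[i] = x[i];
  return v;
}

// padded copy (rows circular, cols zero/reflect) of an (HW x C) activation
arma::fcube pad_act(const fmat& m, int H, int W, int pad_mode) {
  const int C = m.n_cols;
  arma::fcube xp(H + 2, W + 2, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* col = m.colptr(c);
    for (int j = 0; j < W; ++j) {
      const float* src = col + (uword)H * j;
      float* dst = xp.slice_colptr(c, j + 1);
      std::memcpy(dst + 1, src, H * sizeof(float));
      dst[0] = src[H - 1];
      dst[H + 1] = src[0];
    }
    if (pad_mode == 1) {
      std::memcpy(xp.slice_colptr(c, 0), xp.slice_colptr(c, 1),
                  (H + 2) * sizeof(float));
      std::memcpy(xp.slice_colptr(c, W + 1), xp.slice_colptr(c, W),
                  (H + 2) * sizeof(float));
    }
  }
  return xp;
}

fmat im2col(const arma::fcube& xp, int H, int W) {
  const int C = xp.n_slices;
  fmat Kt((uword)H * W, (uword)C * 9);
  for (int c = 0; c < C; ++c)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const uword r = c * 9 + (dj + 1) * 3 + (di + 1);
        float* dst = Kt.colptr(r);
        for (int j = 0; j < W; ++j) {
          const float* src = xp.slice_colptr(c, j + dj + 1) + (di + 1);
          std::memcpy(dst + (uword)H * j, src, H * sizeof(float));
        }
      }
  return Kt;
}

// conv3x3 -> instance norm -> relu (bias-free conv; see R docs)
ConvBlk cir_fwd(const fmat& x, int H, int W, const fmat& w, const fvec& g,
                const fvec& nb, int pad_mode) {
  const int Cout = w.n_cols;
  const uword HW = (uword)H * W;
  fmat y = im2col(pad_act(x, H, W, pad_mode), H, W) * w;
  ConvBlk blk;
  blk.a.set_size(HW, Cout);
  blk.xhat.set_size(HW, Cout);
  blk.s.set_size(Cout);
  for (int c = 0; c < Cout; ++c) {
    float* yc = y.colptr(c);
    double mu = 0, m2 = 0;
    for (uword i = 0; i < HW; ++i) { mu += yc[i]; m2 += (double)yc[i] * yc[i]; }
    mu /= HW; m2 /= HW;
    const float s = std::sqrt((float)(m2 - mu * mu) + 1e-5f);
    const float inv = 1.0f / s, fmu = (float)mu, gg = g[c], bb = nb[c];
    float* xc = blk.xhat.colptr(c);
    float* ac = blk.a.colptr(c);
    for (uword i = 0; i < HW; ++i) {
      const float xh = (yc[i] - fmu) * inv;
      xc[i] = xh;
      const float v = gg * xh + bb;
      ac[i] = v > 0.0f ? v : 0.0f;
    }
    blk.s[c] = s;
  }
  return blk;
}

struct CirGrad {
  fmat dx, dw;
  fvec dg, dnb;
};

CirGrad cir_bwd(const fmat& x, int H, int W, const fmat& w, const fvec& g,
                const ConvBlk& blk, const fmat& dy, int pad_mode) {
  const int Cout = w.n_cols, Cin = x.n_cols;
  const uword HW = (uword)H * W;
  fmat din(HW, Cout);
  CirGrad out;
  out.dg.set_size(Cout);
  out.dnb.set_size(Cout);
  for (int c = 0; c < Cout; ++c) {
    const float* dyv = dy.colptr(c);
    const float* av = blk.a.colptr(c);
    const float* xv = blk.xhat.colptr(c);
    const float gg = g[c], inv = 1.0f / blk.s[c];
    double sdg = 0, sdb = 0, m1 = 0, m2 = 0;
    float* dc = din.colptr(c);
    for (uword i = 0; i < HW; ++i) {
      const float dm = av[i] > 0.0f ? dyv[i] : 0.0f;
      sdg += (double)dm * xv[i];
      sdb += dm;
      const float dxh = gg * dm;
      dc[i] = dxh;
      m1 += dxh;
      m2 += (double)dxh * xv[i];
    }
    out.dg[c] = sdg;
    out.dnb[c] = sdb;
    const float fm1 = (float)(m1 / HW), fm2 = (float)(m2 / HW);
    for (uword i = 0; i < HW; ++i)
      dc[i] = (dc[i] - fm1 - xv[i] * fm2) * inv;
  }
  fmat Kt = im2col(pad_act(x, H, W, pad_mode), H, W);
  out.dw = Kt.t() * din;
  fmat dKt = din * w.t();
  arma::fcube dxp(H + 2, W + 2, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const uword r = c * 9 + (dj + 1) * 3 + (di + 1);
        const float* src = dKt.colptr(r);
        for (int j = 0; j < W; ++j) {
          float* dst = dxp.slice_colptr(c, j + dj + 1) + (di + 1);
          const float* s = src + (uword)H * j;
          for (int i = 0; i < H; ++i) dst[i] += s[i];
        }
      }
  out.dx.zeros(HW, Cin);
  for (int c = 0; c < Cin; ++c) {
    float* col = out.dx.colptr(c);
    for (int j = 0; j < W + 2; ++j) {
      int jj = j - 1;
      if (jj < 0 || jj >= W) {
        if (pad_mode == 0) continue;
        jj = (jj < 0) ? 0 : W - 1;
      }
      const float* src = dxp.slice_colptr(c, j);
      float* dst = col + (uword)H * jj;
      for (int i = 0; i < H; ++i) dst[i] += src[i + 1];
      dst[H - 1] += src[0];
      dst[0] += src[H + 1];
    }
  }
  return out;
}

fmat maxpool_fwd(const fmat& x, int H, int W, arma::uvec& idx) {
  const int C = x.n_cols, Ho = H / 2, Wo = W / 2;
  fmat y((uword)Ho * Wo, C);
  idx.set_size((uword)Ho * Wo * C);
  uword q = 0;
  for (int c = 0; c < C; ++c) {
    const float* col = x.colptr(c);
    float* yc = y.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      const float* cA = col + (uword)H * (2 * j);
      const float* cB = col + (uword)H * (2 * j + 1);
      for (int i = 0; i < Ho; ++i) {
        const float v[4] = {cA[2 * i], cA[2 * i + 1], cB[2 * i], cB[2 * i + 1]};
        int best = 0;
        for (int t = 1; t < 4; ++t) if (v[t] > v[best]) best = t;
        yc[i + (uword)Ho * j] = v[best];
        idx[q++] = (uword)(2 * i + (best & 1)) + (uword)H * (2 * j + (best >> 1)) +
                   (uword)H * W * c;
      }
    }
  }
  return y;
}

fmat maxpool_bwd(const arma::uvec& idx, const fmat& dy, int H, int W, int C) {
  fmat dx((uword)H * W, C, arma::fill::zeros);
  float* p = dx.memptr();
  const float* d = dy.memptr();
  for (uword q = 0; q < idx.n_elem; ++q) p[idx[q]] += d[q];
  return dx;
}

fmat upsample_fwd(const fmat& x, int H, int W) {
  const int C = x.n_cols;
  fmat y((uword)4 * H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* col = x.colptr(c);
    float* yc = y.colptr(c);
    for (int j = 0; j < W; ++j) {
      const float* src = col + (uword)H * j;
      float* d1 = yc + (uword)2 * H * (2 * j);
      float* d2 = yc + (uword)2 * H * (2 * j + 1);
      for (int i = 0; i < H; ++i) {
        d1[2 * i] = d1[2 * i + 1] = src[i];
        d2[2 * i] = d2[2 * i + 1] = src[i];
      }
    }
  }
  return y;
}

fmat upsample_bwd(const fmat& dy, int H, int W) {
  // H, W: coarse dims of the output gradient
  const int C = dy.n_cols;
  fmat dx((uword)H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* col = dy.colptr(c);
    float* dc = dx.colptr(c);
    for (int j = 0; j < W; ++j) {
      const float* s1 = col + (uword)2 * H * (2 * j);
      const float* s2 = col + (uword)2 * H * (2 * j + 1);
      for (int i = 0; i < H; ++i)
        dc[i + (uword)H * j] = s1[2 * i] + s1[2 * i + 1] + s2[2 * i] + s2[2 * i + 1];
    }
  }
  return dx;
}

std::string key(const char* a, int i, const char* b) {
  return std::string(a) + std::to_string(i) + b;
}

bool att_level(const Cache& c, int i) {
  if (!c.attention) return false;
  return i == c.D || i == std::max(1, c.D - 1);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_unet_fwd")]]
List cpp_unet_fwd(List p, NumericMatrix x_, int D, int pad_mode,
                  int attention, bool want_cache) {
  Rcpp::XPtr<Cache> cp(new Cache(), true);
  Cache& C = *cp;
  C.D = D; C.pad_mode = pad_mode; C.attention = attention;
  C.H0 = x_.nrow(); C.W0 = x_.ncol();
  C.lvl.resize(D + 1);
  C.enc_in.resize(D + 1); C.enc1.resize(D + 1); C.enc2.resize(D + 1);
  C.pool_idx.resize(D + 1);
  C.u0.resize(D + 1); C.u.resize(D + 1); C.att_q.resize(D + 1);
  C.att_alpha.resize(D + 1); C.cat.resize(D + 1);
  C.dec1.resize(D + 1); C.dec2.resize(D + 1);

  fmat h((uword)C.H0 * C.W0, 1);
  {
    const double* src = x_.begin();
    float* dst = h.memptr();
    for (uword i = 0; i < h.n_elem; ++i) dst[i] = (float)src[i];
  }
  int H = C.H0, W = C.W0;
  for (int i = 1; i <= D; ++i) {
    C.lvl[i] = {H, W};
    C.enc_in[i] = h;
    C.enc1[i] = cir_fwd(h, H, W, get_w(p, key("enc", i, "_c1_w")),
                        get_v(p, key("enc", i, "_c1_g")),
                        get_v(p, key("enc", i, "_c1_nb")), pad_mode);
    C.enc2[i] = cir_fwd(C.enc1[i].a, H, W, get_w(p, key("enc", i, "_c2_w")),
                        get_v(p, key("enc", i, "_c2_g")),
                        get_v(p, key("enc", i, "_c2_nb")), pad_mode);
    h = maxpool_fwd(C.enc2[i].a, H, W, C.pool_idx[i]);
    H /= 2; W /= 2;
  }
  C.lvl[0] = {H, W};  // bottleneck dims
  C.bot_in = h;
  C.bot1 = cir_fwd(h, H, W, get_w(p, "bot_c1_w"), get_v(p, "bot_c1_g"),
                   get_v(p, "bot_c1_nb"), pad_mode);
  C.bot2 = cir_fwd(C.bot1.a, H, W, get_w(p, "bot_c2_w"),
                   get_v(p, "bot_c2_g"), get_v(p, "bot_c2_nb"), pad_mode);
  h = C.bot2.a;
  for (int i = D; i >= 1; --i) {
    const int Hi = C.lvl[i].H, Wi = C.lvl[i].W;
    C.u0[i] = upsample_fwd(h, Hi / 2, Wi / 2);
    fmat up = get_w(p, key("dec", i, "_up_w"));
    fvec upb = get_v(p, key("dec", i, "_up_b"));
    fmat u = C.u0[i] * up;
    u.each_row() += upb.t();
    u.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
    C.u[i] = u;
    fmat s = C.enc2[i].a;
    if (att_level(C, i)) {
      fmat wg = get_w(p, key("dec", i, "_att_wg"));
      fmat wx = get_w(p, key("dec", i, "_att_wx"));
      fmat psi = get_w(p, key("dec", i, "_att_psi"));
      fvec bg = get_v(p, key("dec", i, "_att_bg"));
      fvec bx = get_v(p, key("dec", i, "_att_bx"));
      fvec bp = get_v(p, key("dec", i, "_att_bp"));
      fmat q = u * wg + s * wx;
      q.each_row() += (bg + bx).t();
      q.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
      fvec alpha = q * psi.col(0) + bp[0];
      alpha.for_each([](float& v) { v = 1.0f / (1.0f + std::exp(-v)); });
      C.att_q[i] = q;
      C.att_alpha[i] = alpha;
      s.each_col() %= alpha;
    }
    C.cat[i] = arma::join_rows(u, s);
    C.dec1[i] = cir_fwd(C.cat[i], Hi, Wi, get_w(p, key("dec", i, "_c1_w")),
                        get_v(p, key("dec", i, "_c1_g")),
                        get_v(p, key("dec", i, "_c1_nb")), pad_mode);
    C.dec2[i] = cir_fwd(C.dec1[i].a, Hi, Wi,
                        get_w(p, key("dec", i, "_c2_w")),
                        get_v(p, key("dec", i, "_c2_g")),
                        get_v(p, key("dec", i, "_c2_nb")), pad_mode);
    h = C.dec2[i].a;
  }
  C.head_in = h;
  fmat wout = get_w(p, "out_w");
  fvec prob = h * wout.col(0) + get_v(p, "out_b")[0];
  prob.for_each([](float& v) { v = 1.0f / (1.0f + std::exp(-v)); });
  C.prob = prob;

  NumericMatrix pm(C.H0, C.W0);
  for (uword i = 0; i < prob.n_elem; ++i) pm[i] = prob[i];
  List out = List::create(_["p"] = pm);
  if (want_cache) out["cache"] = cp;
  return out;
}

// [[Rcpp::export(name = ".cpp_unet_bwd")]]
List cpp_unet_bwd(List p, SEXP cache_, NumericMatrix dprob_) {
  Rcpp::XPtr<Cache> cp(cache_);
  Cache& C = *cp;
  const int D = C.D, pad_mode = C.pad_mode;
  List g;

  fvec dlogit(C.prob.n_elem);
  {
    const double* dp = dprob_.begin();
    for (uword i = 0; i < dlogit.n_elem; ++i) {
      const float pr = C.prob[i];
      dlogit[i] = (float)dp[i] * pr * (1.0f - pr);
    }
  }
  fmat wout = get_w(p, "out_w");
  fvec dwout = C.head_in.t() * dlogit;
  g["out_w"] = put_arr(fmat(dwout), p["out_w"]);
  g["out_b"] = NumericVector::create(arma::accu(dlogit));
  fmat dh = dlogit * wout.col(0).t();

  std::vector<fmat> skip_grad(D + 1);
  for (int i = 1; i <= D; ++i) {
    const int Hi = C.lvl[i].H, Wi = C.lvl[i].W;
    CirGrad g2 = cir_bwd(C.dec1[i].a, Hi, Wi, get_w(p, key("dec", i, "_c2_w")),
                         get_v(p, key("dec", i, "_c2_g")), C.dec2[i], dh,
                         pad_mode);
    g[key("dec", i, "_c2_w")] = put_arr(g2.dw, p[key("dec", i, "_c2_w")]);
    g[key("dec", i, "_c2_b")] = put_vec(fvec(g2.dg.n_elem, arma::fill::zeros));
    g[key("dec", i, "_c2_g")] = put_vec(g2.dg);
    g[key("dec", i, "_c2_nb")] = put_vec(g2.dnb);
    CirGrad g1 = cir_bwd(C.cat[i], Hi, Wi, get_w(p, key("dec", i, "_c1_w")),
                         get_v(p, key("dec", i, "_c1_g")), C.dec1[i], g2.dx,
                         pad_mode);
    g[key("dec", i, "_c1_w")] = put_arr(g1.dw, p[key("dec", i, "_c1_w")]);
    g[key("dec", i, "_c1_b")] = put_vec(fvec(g1.dg.n_elem, arma::fill::zeros));
    g[key("dec", i, "_c1_g")] = put_vec(g1.dg);
    g[key("dec", i, "_c1_nb")] = put_vec(g1.dnb);
    const int ci = C.u[i].n_cols;
    fmat du = g1.dx.cols(0, ci - 1);
    fmat ds_out = g1.dx.cols(ci, 2 * ci - 1);
    fmat ds_skip;
    if (att_level(C, i)) {
      const fmat& S = C.enc2[i].a;
      const fmat& U = C.u[i];
      const fmat& q = C.att_q[i];
      const fvec& alpha = C.att_alpha[i];
      fmat wg = get_w(p, key("dec", i, "_att_wg"));
      fmat wx = get_w(p, key("dec", i, "_att_wx"));
      fmat psi = get_w(p, key("dec", i, "_att_psi"));
      fvec dalpha = arma::sum(ds_out % S, 1);
      fmat dS = ds_out;
      dS.each_col() %= alpha;
      fvec dz = dalpha % alpha % (1.0f - alpha);
      fvec dpsi = q.t() * dz;
      g[key("dec", i, "_att_psi")] = put_arr(fmat(dpsi),
                                             p[key("dec", i, "_att_psi")]);
      g[key("dec", i, "_att_bp")] = NumericVector::create(arma::accu(dz));
      fmat dq = dz * psi.col(0).t();
      for (uword k = 0; k < dq.n_elem; ++k)
        if (q.memptr()[k] <= 0.0f) dq.memptr()[k] = 0.0f;
      g[key("dec", i, "_att_wg")] = put_arr(fmat(U.t() * dq),
                                            p[key("dec", i, "_att_wg")]);
      g[key("dec", i, "_att_wx")] = put_arr(fmat(S.t() * dq),
                                            p[key("dec", i, "_att_wx")]);
      fvec dqs = arma::sum(dq, 0).t();
      g[key("dec", i, "_att_bg")] = put_vec(dqs);
      g[key("dec", i, "_att_bx")] = put_vec(dqs);
      du += dq * wg.t();
      ds_skip = dS + dq * wx.t();
    } else {
      ds_skip = ds_out;
    }
    // through the up-projection relu
    for (uword k = 0; k < du.n_elem; ++k)
      if (C.u[i].memptr()[k] <= 0.0f) du.memptr()[k] = 0.0f;
    fmat up = get_w(p, key("dec", i, "_up_w"));
    g[key("dec", i, "_up_w")] = put_arr(fmat(C.u0[i].t() * du),
                                        p[key("dec", i, "_up_w")]);
    g[key("dec", i, "_up_b")] = put_vec(fvec(arma::sum(du, 0).t()));
    skip_grad[i] = ds_skip;
    dh = upsample_bwd(du * up.t(), Hi / 2, Wi / 2);
  }

  CirGrad b2 = cir_bwd(C.bot1.a, C.lvl[0].H, C.lvl[0].W, get_w(p, "bot_c2_w"),
                       get_v(p, "bot_c2_g"), C.bot2, dh, pad_mode);
  g["bot_c2_w"] = put_arr(b2.dw, p["bot_c2_w"]);
  g["bot_c2_b"] = put_vec(fvec(b2.dg.n_elem, arma::fill::zeros));
  g["bot_c2_g"] = put_vec(b2.dg);
  g["bot_c2_nb"] = put_vec(b2.dnb);
  CirGrad b1 = cir_bwd(C.bot_in, C.lvl[0].H, C.lvl[0].W, get_w(p, "bot_c1_w"),
                       get_v(p, "bot_c1_g"), C.bot1, b2.dx, pad_mode);
  g["bot_c1_w"] = put_arr(b1.dw, p["bot_c1_w"]);
  g["bot_c1_b"] = put_vec(fvec(b1.dg.n_elem, arma::fill::zeros));
  g["bot_c1_g"] = put_vec(b1.dg);
  g["bot_c1_nb"] = put_vec(b1.dnb);
  dh = b1.dx;

  for (int i = D; i >= 1; --i) {
    const int Hi = C.lvl[i].H, Wi = C.lvl[i].W;
    fmat dskip = maxpool_bwd(C.pool_idx[i], dh, Hi, Wi, dh.n_cols);
    dskip += skip_grad[i];
    CirGrad g2 = cir_bwd(C.enc1[i].a, Hi, Wi, get_w(p, key("enc", i, "_c2_w")),
                         get_v(p, key("enc", i, "_c2_g")), C.enc2[i], dskip,
                         pad_mode);
    g[key("enc", i, "_c2_w")] = put_arr(g2.dw, p[key("enc", i, "_c2_w")]);
    g[key("enc", i, "_c2_b")] = put_vec(fvec(g2.dg.n_elem, arma::fill::zeros));
    g[key("enc", i, "_c2_g")] = put_vec(g2.dg);
    g[key("enc", i, "_c2_nb")] = put_vec(g2.dnb);
    CirGrad g1 = cir_bwd(C.enc_in[i], Hi, Wi, get_w(p, key("enc", i, "_c1_w")),
                         get_v(p, key("enc", i, "_c1_g")), C.enc1[i], g2.dx,
                         pad_mode);
    g[key("enc", i, "_c1_w")] = put_arr(g1.dw, p[key("enc", i, "_c1_w")]);
    g[key("enc", i, "_c1_b")] = put_vec(fvec(g1.dg.n_elem, arma::fill::zeros));
    g[key("enc", i, "_c1_g")] = put_vec(g1.dg);
    g[key("enc", i, "_c1_nb")] = put_vec(g1.dnb);
    dh = g1.dx;
  }
  *cp = Cache();   // the cache is single-use; free its buffers eagerly
  return g;
}
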