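// Single-precision variants of the convolution kernels, used for network
// training where float32 arithmetic is standard practice; the
// double-precision kernels in conv_ops.cpp remain the reference
// implementation the gradient checks pin down.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_f(const double* x, int H, int W, int C, int KH, int KW,
                     arma::fmat& P) {
  const int HO = H - KH + 1, WO = W - KW + 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * c);
        float* pcol = P.colptr(col);
        for (int wo = 0; wo < WO; ++wo) {
          const double* src = xc + (std::size_t)(wo + kw) * H + kh;
          float* dst = pcol + (std::size_t)wo * HO;
          for (int ho = 0; ho < HO; ++ho) dst[ho] = (float)src[ho];
        }
      }
    }
  }
}

static void col2im_add_f(const arma::fmat& P, int H, int W, int C, int KH,
                         int KW, double* dx) {
  const int HO = H - KH + 1, WO = W - KW + 1;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * c);
        const float* pcol = P.colptr(col);
        for (int wo = 0; wo < WO; ++wo) {
          double* dst = xc + (std::size_t)(wo + kw) * H + kh;
          const float* src = pcol + (std::size_t)wo * HO;
          for (int ho = 0; ho < HO; ++ho) dst[ho] += (double)src[ho];
        }
      }
    }
  }
}

static arma::fmat to_fmat(const double* p, std::size_t nr, std::size_t nc) {
  arma::fmat M(nr, nc);
  float* dst = M.memptr();
  for (std::size_t i = 0; i < nr * nc; ++i) dst[i] = (float)p[i];
  return M;
}

// [[Rcpp::export(name = ".conv2d_fwd_f32")]]
NumericVector conv2d_fwd_f32(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel count does not match input");
  const int HO = H - KH + 1, WO = W - KW + 1;
  if (HO < 1 || WO < 1) stop("input smaller than the convolution kernel");
  NumericVector out((std::size_t)HO * WO * F * B);
  arma::fmat Wm = to_fmat(w.begin(), (std::size_t)KH * KW * C, F);
  arma::frowvec bv((std::size_t)F);
  for (int f = 0; f < F; ++f) bv[f] = (float)b[f];
  arma::fmat P(HO * WO, KH * KW * C);
  arma::fmat O;
  for (int s = 0; s < B; ++s) {
    im2col_f(x.begin() + (std::size_t)s * H * W * C, H, W, C, KH, KW, P);
    O = P * Wm;
    O.each_row() += bv;
    double* op = out.begin() + (std::size_t)s * HO * WO * F;
    const float* sp = O.memptr();
    for (std::size_t i = 0; i < (std::size_t)HO * WO * F; ++i) op[i] = (double)sp[i];
  }
  out.attr("dim") = IntegerVector::create(HO, WO, F, B);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd_f32")]]
List conv2d_bwd_f32(NumericVector x, NumericVector w, NumericVector dout,
                    bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  const int HO = H - KH + 1, WO = W - KW + 1;
  NumericVector dx((std::size_t)H * W * C * B);
  NumericVector dw((std::size_t)KH * KW * C * F);
  NumericVector db(F);
  arma::fmat Wm = to_fmat(w.begin(), (std::size_t)KH * KW * C, F);
  arma::fmat dWm((std::size_t)KH * KW * C, F, arma::fill::zeros);
  arma::frowvec dbv(F, arma::fill::zeros);
  arma::fmat P(HO * WO, KH * KW * C);
  for (int s = 0; s < B; ++s) {
    arma::fmat dO = to_fmat(dout.begin() + (std::size_t)s * HO * WO * F,
                            (std::size_t)HO * WO, F);
    im2col_f(x.begin() + (std::size_t)s * H * W * C, H, W, C, KH, KW, P);
    dWm += P.t() * dO;
    dbv += arma::sum(dO, 0);
    if (need_dx) {
      arma::fmat dP = dO * Wm.t();
      col2im_add_f(dP, H, W, C, KH, KW, dx.begin() + (std::size_t)s * H * W * C);
    }
  }
  double* dwp = dw.begin();
  const float* sp = dWm.memptr();
  for (std::size_t i = 0; i < (std::size_t)KH * KW * C * F; ++i) dwp[i] = (double)sp[i];
  for (int f = 0; f < F; ++f) db[f] = (double)dbv[f];
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Cached-forward variant: returns the float patch matrices alongside the
// output so the backward pass can skip rebuilding them.
struct ConvCache {
  std::vector<arma::fmat> P;
  int H, W, C, KH, KW;
};

// [[Rcpp::export(name = ".conv2d_fwd_f32c")]]
List conv2d_fwd_f32c(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel count does not match input");
  const int HO = H - KH + 1, WO = W - KW + 1;
  if (HO < 1 || WO < 1) stop("input smaller than the convolution kernel");
  NumericVector out((std::size_t)HO * WO * F * B);
  arma::fmat Wm = to_fmat(w.begin(), (std::size_t)KH * KW * C, F);
  arma::frowvec bv((std::size_t)F);
  for (int f = 0; f < F; ++f) bv[f] = (float)b[f];
  Rcpp::XPtr<ConvCache> cache(new ConvCache());
  cache->H = H; cache->W = W; cache->C = C; cache->KH = KH; cache->KW = KW;
  cache->P.resize(B);
  arma::fmat O;
  for (int s = 0; s < B; ++s) {
    cache->P[s].set_size(HO * WO, KH * KW * C);
    im2col_f(x.begin() + (std::size_t)s * H * W * C, H, W, C, KH, KW,
             cache->P[s]);
    O = cache->P[s] * Wm;
    O.each_row() += bv;
    double* op = out.begin() + (std::size_t)s * HO * WO * F;
    const float* sp = O.memptr();
    for (std::size_t i = 0; i < (std::size_t)HO * WO * F; ++i) op[i] = (double)sp[i];
  }
  out.attr("dim") = IntegerVector::create(HO, WO, F, B);
  return List::create(_["out"] = out, _["cache"] = cache);
}

// [[Rcpp::export(name = ".conv2d_bwd_f32c")]]
List conv2d_bwd_f32c(SEXP cache_xp, NumericVector w, NumericVector dout,
                     bool need_dx = true) {
  Rcpp::XPtr<ConvCache> cache(cache_xp);
  IntegerVector wd = w.attr("dim");
  const int H = cache->H, W = cache->W, C = cache->C;
  const int KH = cache->KH, KW = cache->KW, F = wd[3];
  const int HO = H - KH + 1, WO = W - KW + 1;
  const int B = (int)cache->P.size();
  NumericVector dx((std::size_t)H * W * C * B);
  NumericVector dw((std::size_t)KH * KW * C * F);
  NumericVector db(F);
  arma::fmat Wm = to_fmat(w.begin(), (std::size_t)KH * KW * C, F);
  arma::fmat dWm((std::size_t)KH * KW * C, F, arma::fill::zeros);
  arma::frowvec dbv(F, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    arma::fmat dO = to_fmat(dout.begin() + (std::size_t)s * HO * WO * F,
                            (std::size_t)HO * WO, F);
    dWm += cache->P[s].t() * dO;
    dbv += arma::sum(dO, 0);
    if (need_dx) {
      arma::fmat dP = dO * Wm.t();
      col2im_add_f(dP, H, W, C, KH, KW, dx.begin() + (std::size_t)s * H * W * C);
    }
  }
  double* dwp = dw.begin();
  const float* sp = dWm.memptr();
  for (std::size_t i = 0; i < (std::size_t)KH * KW * C * F; ++i) dwp[i] = (double)sp[i];
  for (int f = 0; f < F; ++f) db[f] = (double)dbv[f];
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
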