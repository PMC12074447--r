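// Minimal 2-D convolution and max-pooling kernels (valid padding, stride 1)
// for the spectrogram CNN.  Layout follows R arrays column-major:
// inputs  x : [H, W, C, B]
// filters w : [KH, KW, C, F]
// outputs   : [HO, WO, F, B] with HO = H-KH+1, WO = W-KW+1.
// The convolution is implemented as im2col + GEMM per sample; the patch
// matrix is rebuilt in the backward pass instead of cached, which keeps
// peak memory at one sample's patches.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int KH, int KW,
                   arma::mat& P) {
  const int HO = H - KH + 1, WO = W - KW + 1;
  // P : (HO*WO) x (KH*KW*C); column index runs kh fastest, then kw, then c
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * c);
        double* pcol = P.colptr(col);
        for (int wo = 0; wo < WO; ++wo) {
          const double* src = xc + (std::size_t)(wo + kw) * H + kh;
          std::memcpy(pcol + (std::size_t)wo * HO, src, HO * sizeof(double));
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& P, int H, int W, int C, int KH, int KW,
                       double* dx) {
  const int HO = H - KH + 1, WO = W - KW + 1;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * c);
        const double* pcol = P.colptr(col);
        for (int wo = 0; wo < WO; ++wo) {
          double* dst = xc + (std::size_t)(wo + kw) * H + kh;
          const double* src = pcol + (std::size_t)wo * HO;
          for (int ho = 0; ho < HO; ++ho) dst[ho] += src[ho];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel count does not match input");
  const int HO = H - KH + 1, WO = W - KW + 1;
  if (HO < 1 || WO < 1) stop("input smaller than the convolution kernel");
  NumericVector out((std::size_t)HO * WO * F * B);
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)KH * KW * C, F, false);
  arma::rowvec bv(const_cast<double*>(b.begin()), F, false);
  arma::mat P(HO * WO, KH * KW * C);
  for (int s = 0; s < B; ++s) {
    im2col(x.begin() + (std::size_t)s * H * W * C, H, W, C, KH, KW, P);
    arma::mat O(out.begin() + (std::size_t)s * HO * WO * F, HO * WO, F, false, true);
    O = P * Wm;
    O.each_row() += bv;
  }
  out.attr("dim") = IntegerVector::create(HO, WO, F, B);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  const int HO = H - KH + 1, WO = W - KW + 1;
  NumericVector dx((std::size_t)H * W * C * B);
  NumericVector dw((std::size_t)KH * KW * C * F);
  NumericVector db(F);
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)KH * KW * C, F, false);
  arma::mat dWm(dw.begin(), (std::size_t)KH * KW * C, F, false, true);
  arma::rowvec dbv(db.begin(), F, false, true);
  arma::mat P(HO * WO, KH * KW * C);
  for (int s = 0; s < B; ++s) {
    arma::mat dO(const_cast<double*>(dout.begin()) + (std::size_t)s * HO * WO * F,
                 HO * WO, F, false);
    im2col(x.begin() + (std::size_t)s * H * W * C, H, W, C, KH, KW, P);
    dWm += P.t() * dO;
    dbv += arma::sum(dO, 0);
    if (need_dx) {
      arma::mat dP = dO * Wm.t();
      col2im_add(dP, H, W, C, KH, KW, dx.begin() + (std::size_t)s * H * W * C);
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor semantics on odd dims.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int HO = H / 2, WO = W / 2;
  NumericVector out((std::size_t)HO * WO * C * B);
  IntegerVector amax((std::size_t)HO * WO * C * B);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amax.begin();
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base_in = ((std::size_t)s * C + c) * H * W;
      const std::size_t base_out = ((std::size_t)s * C + c) * HO * WO;
      for (int wo = 0; wo < WO; ++wo) {
        for (int ho = 0; ho < HO; ++ho) {
          std::size_t i00 = base_in + (std::size_t)(2 * wo) * H + 2 * ho;
          std::size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (xp[cand[k]] > xp[cand[best]]) best = k;
          op[base_out + (std::size_t)wo * HO + ho] = xp[cand[best]];
          ap[base_out + (std::size_t)wo * HO + ho] = (int)(cand[best] - base_in);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(HO, WO, C, B);
  amax.attr("dim") = IntegerVector::create(HO, WO, C, B);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector amax, NumericVector dout,
                           IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], B = in_dim[3];
  IntegerVector od = dout.attr("dim");
  const int HO = od[0], WO = od[1];
  NumericVector dx((std::size_t)H * W * C * B);
  const double* dop = dout.begin();
  const int* ap = amax.begin();
  double* dxp = dx.begin();
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base_in = ((std::size_t)s * C + c) * H * W;
      const std::size_t base_out = ((std::size_t)s * C + c) * HO * WO;
      for (std::size_t k = 0; k < (std::size_t)HO * WO; ++k) {
        dxp[base_in + ap[base_out + k]] += dop[base_out + k];
      }
    }
  }
  dx.attr("dim") = in_dim;
  return dx;
}
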