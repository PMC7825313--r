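// Low-level tensor kernels for the network engine.
//
// Tensors are R arrays dim c(H, W, C), column-major, so element (h, w, c)
// sits at h + H*w + H*W*c.  Convolution weights are arrays dim
// c(k, k, c_in, c_out).  All convolutions use size-preserving padding
// (pad = dilation*(k-1)/2), stride 1; pooling and transposed convolution
// use kernel 2, stride 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fill the im2col matrix A [H*W, k*k*C] for a dilated, zero-padded,
// size-preserving convolution.  Column j = kh + k*kw + k*k*c.
static void im2col(const double* x, int H, int W, int C,
                   int k, int dil, arma::mat& A) {
  const int pad = dil * (k - 1) / 2;
  A.zeros(static_cast<arma::uword>(H) * W, static_cast<arma::uword>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(H) * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const arma::uword col = kh + k * kw + k * k * c;
        const int dh = kh * dil - pad, dw = kw * dil - pad;
        double* acol = A.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* src = xc + static_cast<size_t>(H) * sw + (h0 + dh);
          double* dst = acol + static_cast<size_t>(H) * w + h0;
          for (int h = h0; h < h1; ++h) *dst++ = *src++;
        }
      }
    }
  }
}

// Scatter-add of the im2col-shaped gradient back to input layout.
static void col2im(const arma::mat& A, int H, int W, int C,
                   int k, int dil, double* gx) {
  const int pad = dil * (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + static_cast<size_t>(H) * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const arma::uword col = kh + k * kw + k * k * c;
        const int dh = kh * dil - pad, dw = kw * dil - pad;
        const double* acol = A.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          double* dst = gc + static_cast<size_t>(H) * sw + (h0 + dh);
          const double* src = acol + static_cast<size_t>(H) * w + h0;
          for (int h = h0; h < h1; ++h) *dst++ += *src++;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wt,
                             NumericVector bias, int dil) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, wd[2]);
  arma::mat A;
  im2col(x.begin(), H, W, C, k, dil, A);
  const arma::mat Wm(const_cast<double*>(wt.begin()),
                     static_cast<arma::uword>(k) * k * C, Cout, false, true);
  arma::mat Y = A * Wm;
  if (bias.size() == Cout) Y.each_row() += arma::rowvec(bias.begin(), Cout);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wt, NumericVector gout,
                    int dil, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  arma::mat A;
  im2col(x.begin(), H, W, C, k, dil, A);
  const arma::mat G(const_cast<double*>(gout.begin()),
                    static_cast<arma::uword>(H) * W, Cout, false, true);
  const arma::mat Wm(const_cast<double*>(wt.begin()),
                     static_cast<arma::uword>(k) * k * C, Cout, false, true);
  arma::mat gW = A.t() * G;
  arma::mat gA = G * Wm.t();
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  col2im(gA, H, W, C, k, dil, gx.begin());
  gx.attr("dim") = IntegerVector::create(H, W, C);
  NumericVector gWout(gW.begin(), gW.end());
  gWout.attr("dim") = wd;
  List res = List::create(_["gx"] = gx, _["gW"] = gWout);
  if (has_bias) {
    arma::rowvec gb = arma::sum(G, 0);
    res["gb"] = NumericVector(gb.begin(), gb.end());
  }
  return res;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping): every input
// pixel paints one 2x2 output block.  out[2i+a, 2j+b, co] =
// sum_ci x[i,j,ci] * W[a,b,ci,co].  No bias (the graphs do not use one).
// [[Rcpp::export]]
NumericVector cpp_tconv2_fwd(NumericVector x, NumericVector wt) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], Cout = wd[3];
  if (wd[2] != C) stop("tconv2: channel mismatch");
  const arma::mat X(const_cast<double*>(x.begin()),
                    static_cast<arma::uword>(H) * W, C, false, true);
  // Wm: [C, 4*Cout], column (a + 2*b + 4*co) <- W[a,b,ci,co]
  arma::mat Wm(C, 4 * Cout);
  const double* wp = wt.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          Wm(ci, a + 2 * b + 4 * co) = wp[a + 2 * b + 4 * ci + 4 * C * co];
  arma::mat Y = X * Wm;  // [H*W, 4*Cout]
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout);
  double* op = out.begin();
  for (int co = 0; co < Cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        const double* yc = Y.colptr(a + 2 * b + 4 * co);
        double* oc = op + static_cast<size_t>(Ho) * Wo * co;
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            oc[(2 * h + a) + static_cast<size_t>(Ho) * (2 * w + b)] =
                yc[h + static_cast<size_t>(H) * w];
      }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_tconv2_bwd(NumericVector x, NumericVector wt, NumericVector gout) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  // Gather gout into [H*W, 4*Cout]
  arma::mat G(static_cast<arma::uword>(H) * W, 4 * Cout);
  const double* gp = gout.begin();
  for (int co = 0; co < Cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        double* gc = G.colptr(a + 2 * b + 4 * co);
        const double* oc = gp + static_cast<size_t>(Ho) * Wo * co;
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            gc[h + static_cast<size_t>(H) * w] =
                oc[(2 * h + a) + static_cast<size_t>(Ho) * (2 * w + b)];
      }
  const arma::mat X(const_cast<double*>(x.begin()),
                    static_cast<arma::uword>(H) * W, C, false, true);
  arma::mat Wm(C, 4 * Cout);
  const double* wp = wt.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          Wm(ci, a + 2 * b + 4 * co) = wp[a + 2 * b + 4 * ci + 4 * C * co];
  arma::mat gX = G * Wm.t();
  arma::mat gWm = X.t() * G;  // [C, 4*Cout]
  NumericVector gW(wt.size());
  double* gwp = gW.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          gwp[a + 2 * b + 4 * ci + 4 * C * co] = gWm(ci, a + 2 * b + 4 * co);
  gW.attr("dim") = wd;
  NumericVector gx(gX.begin(), gX.end());
  gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// 2x2 stride-2 max pooling; returns pooled map and 1-based argmax indices
// into the flattened input, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C);
  IntegerVector idx(out.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const size_t xoff = static_cast<size_t>(H) * W * c;
    const size_t ooff = static_cast<size_t>(Ho) * Wo * c;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        size_t best = xoff + (2 * h) + static_cast<size_t>(H) * (2 * w);
        double bv = xp[best];
        const int hh[2] = {2 * h, 2 * h + 1}, ww[2] = {2 * w, 2 * w + 1};
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const size_t p = xoff + hh[a] + static_cast<size_t>(H) * ww[b];
            if (xp[p] > bv) { bv = xp[p]; best = p; }
          }
        const size_t o = ooff + h + static_cast<size_t>(Ho) * w;
        out[o] = bv;
        idx[o] = static_cast<int>(best) + 1;
      }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gout, IntegerVector idx,
                               IntegerVector in_dim) {
  NumericVector gx(static_cast<R_xlen_t>(in_dim[0]) * in_dim[1] * in_dim[2]);
  const double* gp = gout.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gp[i];
  gx.attr("dim") = in_dim;
  return gx;
}
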