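// Low-level image-tensor primitives shared by the scale-adaptation
// autoencoder and the dense backbone. Tensors are base-R numeric arrays
// with dim = c(H, W, C) (column-major, matching R's array layout).
//
// Convolutions are im2col + GEMM; the im2col row ordering
// (ki + kh*(kj + kw*c)) matches the column-major layout of a weight
// array with dim = c(kh, kw, Cin, Cout), so the weight array can be
// viewed as a (kh*kw*Cin) x Cout matrix without copying.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::cube view_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector cube_to_r(const arma::mat& m, int H, int W, int C) {
  NumericVector out(m.begin(), m.end());
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int jin = oj * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int iin = oi * stride - pad + ki;
            if (iin < 0 || iin >= H) continue;
            cols(r, oi + Ho * oj) = x(iin, jin, c);
          }
        }
      }
  return cols;
}

static void col2im(const arma::mat& cols, arma::cube& x, int kh, int kw,
                   int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int jin = oj * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int iin = oi * stride - pad + ki;
            if (iin < 0 || iin >= H) continue;
            x(iin, jin, c) += cols(r, oi + Ho * oj);
          }
        }
      }
}

static void conv_out_size(int H, int W, int kh, int kw, int stride, int pad,
                          int& Ho, int& Wo) {
  Ho = (H + 2 * pad - kh) / stride + 1;
  Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input too small for kernel/stride/padding");
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  arma::cube xc = view_cube(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must have dim (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if ((int)xc.n_slices != Cin) stop("conv2d: input has %d channels, weights expect %d",
                                    (int)xc.n_slices, Cin);
  int Ho, Wo;
  conv_out_size(xc.n_rows, xc.n_cols, kh, kw, stride, pad, Ho, Wo);
  arma::mat cols = im2col(xc, kh, kw, stride, pad, Ho, Wo);
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat out = cols.t() * wm;                 // (Ho*Wo) x Cout
  arma::rowvec b(const_cast<double*>(bias.begin()), Cout, false, true);
  out.each_row() += b;
  return cube_to_r(out, Ho, Wo, Cout);
}

// Gradients of mean-agnostic conv: gout has dim (Ho, Wo, Cout).
// [[Rcpp::export]]
List cpp_conv2d_grad(NumericVector x, NumericVector w, NumericVector gout,
                     int stride, int pad) {
  arma::cube xc = view_cube(x);
  arma::cube gc = view_cube(gout);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gc.n_rows, Wo = gc.n_cols;
  arma::mat G(const_cast<double*>(gout.begin()), Ho * Wo, Cout, false, true);
  arma::mat cols = im2col(xc, kh, kw, stride, pad, Ho, Wo);
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);

  arma::mat dw = cols * G;                       // K x Cout
  arma::rowvec db = arma::sum(G, 0);
  arma::mat dcols = wm * G.t();                  // K x (Ho*Wo)
  arma::cube dx(xc.n_rows, xc.n_cols, Cin, arma::fill::zeros);
  col2im(dcols, dx, kh, kw, stride, pad, Ho, Wo);

  NumericVector dwr(dw.begin(), dw.end());
  dwr.attr("dim") = wd;
  NumericVector dxr(dx.begin(), dx.end());
  dxr.attr("dim") = IntegerVector::create(xc.n_rows, xc.n_cols, Cin);
  return List::create(_["dx"] = dxr, _["dw"] = dwr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad) {
  arma::cube xc = view_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  int Ho, Wo;
  conv_out_size(H, W, k, k, stride, pad, Ho, Wo);
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);                // 1-based linear index into x
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int jin = oj * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int iin = oi * stride - pad + ki;
            if (iin < 0 || iin >= H) continue;
            const double v = xc(iin, jin, c);
            if (v > best) { best = v; besti = iin + H * jin + H * W * c; }
          }
        }
        out[oi + Ho * (oj + Wo * c)] = best;
        idx[oi + Ho * (oj + Wo * c)] = besti + 1;
      }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_grad(IntegerVector idx, NumericVector gout,
                               int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (int i = 0; i < idx.size(); ++i) dx[idx[i] - 1] += gout[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Average pooling over full k x k windows (trailing rows/cols dropped).
// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int k, int stride) {
  arma::cube xc = view_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input too small for average pooling");
  arma::cube out(Ho, Wo, C, arma::fill::zeros);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        double s = 0.0;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            s += xc(oi * stride + ki, oj * stride + kj, c);
        out(oi, oj, c) = s * inv;
      }
  NumericVector r(out.begin(), out.end());
  r.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return r;
}

// Separable resize weights along one axis. mode 0 = bilinear (half-pixel
// centres), mode 1 = area (box overlap; exact antialiased downsampling).
static arma::mat resize_weights(int n_out, int n_in, int mode) {
  arma::mat Wm(n_out, n_in, arma::fill::zeros);
  if (mode == 0) {
    const double scale = (double)n_in / n_out;
    for (int o = 0; o < n_out; ++o) {
      double s = (o + 0.5) * scale - 0.5;
      if (s < 0) s = 0;
      if (s > n_in - 1) s = n_in - 1;
      const int i0 = (int)std::floor(s);
      const int i1 = std::min(i0 + 1, n_in - 1);
      const double f = s - i0;
      Wm(o, i0) += 1.0 - f;
      Wm(o, i1) += f;
    }
  } else {
    const double scale = (double)n_in / n_out;
    for (int o = 0; o < n_out; ++o) {
      const double lo = o * scale, hi = (o + 1) * scale;
      for (int i = (int)std::floor(lo); i < n_in && i < hi; ++i) {
        const double overlap = std::min(hi, (double)i + 1) - std::max(lo, (double)i);
        if (overlap > 0) Wm(o, i) = overlap / scale;
      }
    }
  }
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_resize(NumericVector x, int Ho, int Wo, int mode) {
  arma::cube xc = view_cube(x);
  arma::mat Wr = resize_weights(Ho, xc.n_rows, mode);
  arma::mat Wc = resize_weights(Wo, xc.n_cols, mode);
  arma::cube out(Ho, Wo, xc.n_slices);
  for (unsigned c = 0; c < xc.n_slices; ++c)
    out.slice(c) = Wr * xc.slice(c) * Wc.t();
  NumericVector r(out.begin(), out.end());
  r.attr("dim") = IntegerVector::create(Ho, Wo, (int)xc.n_slices);
  return r;
}

// Adjoint of cpp_resize: pulls a gradient at (Ho, Wo) back to (H, W).
// [[Rcpp::export]]
NumericVector cpp_resize_grad(NumericVector gout, int H, int W, int mode) {
  arma::cube gc = view_cube(gout);
  arma::mat Wr = resize_weights(gc.n_rows, H, mode);
  arma::mat Wc = resize_weights(gc.n_cols, W, mode);
  arma::cube dx(H, W, gc.n_slices);
  for (unsigned c = 0; c < gc.n_slices; ++c)
    dx.slice(c) = Wr.t() * gc.slice(c) * Wc;
  NumericVector r(dx.begin(), dx.end());
  r.attr("dim") = IntegerVector::create(H, W, (int)gc.n_slices);
  return r;
}
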