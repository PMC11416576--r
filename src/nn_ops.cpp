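// Low-level tensor kernels for the network engine.
//
// Conventions (fixed; the R graph code depends on them):
//  * activations are H x W x C arma::cubes (column-major, same memory layout
//    as an R array with dim c(H, W, C));
//  * a k_h x k_w convolution weight is a (k_h*k_w*C_in) x F matrix whose row
//    index is q = dh + k_h*dw + k_h*k_w*c for kernel offset (dh, dw) and input
//    channel c; "same" zero padding, odd kernel sizes only;
//  * a 2x2 stride-2 transposed-convolution weight is a C_in x (4*F) matrix,
//    column j*F + f holding the tap for output sub-position j = dh + 2*dw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d(x.attr("dim"));
  if (d.size() != 3) stop("expected a 3-d array");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector cube_to_r(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// Zero-padded "same" im2col: (H*W) x (kh*kw*C)
static arma::mat im2col(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat col(H * (arma::uword)W, kh * kw * (arma::uword)C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int q = dh + kh * dw + kh * kw * c;
        const int oh = dh - ph, ow = dw - pw;            // source offset
        const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        if (h1 <= h0) continue;
        for (int w = std::max(0, -ow); w < std::min(W, W - ow); ++w) {
          // destination rows h0..h1-1 at output column w; source column w+ow
          std::memcpy(col.colptr(q) + (arma::uword)w * H + h0,
                      x.slice_colptr(c, w + ow) + h0 + oh,
                      (h1 - h0) * sizeof(double));
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col: scatter-add a (H*W) x (kh*kw*C) gradient back to H x W x C
static arma::cube col2im(const arma::mat& gcol, int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int q = dh + kh * dw + kh * kw * c;
        const int oh = dh - ph, ow = dw - pw;
        const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        if (h1 <= h0) continue;
        for (int w = std::max(0, -ow); w < std::min(W, W - ow); ++w) {
          double* dst = gx.slice_colptr(c, w + ow) + oh;
          const double* src = gcol.colptr(q) + (arma::uword)w * H;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix K, NumericVector b,
                             int kh, int kw) {
  arma::cube xc = as_cube(x);
  arma::mat Km(K.begin(), K.nrow(), K.ncol(), false);
  arma::mat y;
  if (kh == 1 && kw == 1) {
    arma::mat X(xc.memptr(), xc.n_rows * xc.n_cols, xc.n_slices, false);
    y = X * Km;
  } else {
    y = im2col(xc, kh, kw) * Km;
  }
  y.each_row() += arma::rowvec(b.begin(), b.size(), false);
  arma::cube out(y.memptr(), xc.n_rows, xc.n_cols, Km.n_cols, true);
  return cube_to_r(out);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix K, NumericVector gy,
                    int kh, int kw) {
  arma::cube xc = as_cube(x), gyc = as_cube(gy);
  arma::mat Km(K.begin(), K.nrow(), K.ncol(), false);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  arma::mat gym(gyc.memptr(), (arma::uword)H * W, gyc.n_slices, false);
  arma::rowvec gb = arma::sum(gym, 0);
  arma::mat gK, gcol;
  arma::cube gx;
  if (kh == 1 && kw == 1) {
    arma::mat X(xc.memptr(), (arma::uword)H * W, C, false);
    gK = X.t() * gym;
    arma::mat gX = gym * Km.t();
    gx = arma::cube(gX.memptr(), H, W, C, true);
  } else {
    arma::mat col = im2col(xc, kh, kw);
    gK = col.t() * gym;
    gcol = gym * Km.t();
    gx = col2im(gcol, H, W, C, kh, kw);
  }
  return List::create(_["gx"] = cube_to_r(gx),
                      _["gW"] = wrap(gK),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericMatrix K, NumericVector b) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int F = K.ncol() / 4;
  arma::mat Km(K.begin(), K.nrow(), K.ncol(), false);
  arma::mat X(xc.memptr(), (arma::uword)H * W, C, false);
  arma::mat y = X * Km;                       // (H*W) x (4F)
  arma::cube out(2 * H, 2 * W, F);
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    for (int j = 0; j < 4; ++j) {
      const int dh = j % 2, dw = j / 2;
      const double* src = y.colptr(j * F + f);
      for (int w = 0; w < W; ++w) {
        double* dst = out.slice_colptr(f, 2 * w + dw) + dh;
        const double* s = src + (arma::uword)w * H;
        for (int h = 0; h < H; ++h) dst[2 * h] = s[h] + bf;
      }
    }
  }
  return cube_to_r(out);
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericMatrix K, NumericVector gy) {
  arma::cube xc = as_cube(x), gyc = as_cube(gy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int F = gyc.n_slices;
  arma::mat Km(K.begin(), K.nrow(), K.ncol(), false);
  arma::mat gym((arma::uword)H * W, 4 * (arma::uword)F);
  NumericVector gb(F);
  for (int f = 0; f < F; ++f) {
    double acc = 0.0;
    for (int j = 0; j < 4; ++j) {
      const int dh = j % 2, dw = j / 2;
      double* dst = gym.colptr(j * F + f);
      for (int w = 0; w < W; ++w) {
        const double* src = gyc.slice_colptr(f, 2 * w + dw) + dh;
        double* d = dst + (arma::uword)w * H;
        for (int h = 0; h < H; ++h) { d[h] = src[2 * h]; acc += src[2 * h]; }
      }
    }
    gb[f] = acc;
  }
  arma::mat X(xc.memptr(), (arma::uword)H * W, C, false);
  arma::mat gK = X.t() * gym;
  arma::mat gX = gym * Km.t();
  arma::cube gx(gX.memptr(), H, W, C, true);
  return List::create(_["gx"] = cube_to_r(gx), _["gW"] = wrap(gK), _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx((arma::uword)Ho * Wo * C);   // winning sub-position 0..3
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = xc(2 * h, 2 * w, c);
        int bj = 0;
        for (int j = 1; j < 4; ++j) {
          const double v = xc(2 * h + j % 2, 2 * w + j / 2, c);
          if (v > best) { best = v; bj = j; }
        }
        y(h, w, c) = best;
        ip[h + (arma::uword)Ho * w + (arma::uword)Ho * Wo * c] = bj;
      }
  return List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy, int H, int W) {
  arma::cube gyc = as_cube(gy);
  const int Ho = gyc.n_rows, Wo = gyc.n_cols, C = gyc.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int j = ip[h + (arma::uword)Ho * w + (arma::uword)Ho * Wo * c];
        gx(2 * h + j % 2, 2 * w + j / 2, c) += gyc(h, w, c);
      }
  return cube_to_r(gx);
}

// [[Rcpp::export]]
NumericVector cpp_meanpool2(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int Ho = xc.n_rows / 2, Wo = xc.n_cols / 2, C = xc.n_slices;
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        y(h, w, c) = 0.25 * (xc(2 * h, 2 * w, c) + xc(2 * h + 1, 2 * w, c) +
                             xc(2 * h, 2 * w + 1, c) + xc(2 * h + 1, 2 * w + 1, c));
  return cube_to_r(y);
}

// Nearest-neighbour upsampling by an integer factor, and its adjoint
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, int factor) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  arma::cube y(H * factor, W * factor, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W * factor; ++w)
      for (int h = 0; h < H * factor; ++h)
        y(h, w, c) = xc(h / factor, w / factor, c);
  return cube_to_r(y);
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector gy, int factor) {
  arma::cube gyc = as_cube(gy);
  const int Ho = gyc.n_rows / factor, Wo = gyc.n_cols / factor, C = gyc.n_slices;
  arma::cube gx(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < (int)gyc.n_cols; ++w)
      for (int h = 0; h < (int)gyc.n_rows; ++h)
        gx(h / factor, w / factor, c) += gyc(h, w, c);
  return cube_to_r(gx);
}
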