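// Convolution / pooling / upsampling kernels for the U-Net engine.
// All image batches are R arrays with dim (H, W, C, N), column-major, so a
// single sample is an H x W x C arma::cube sitting contiguously in memory.
// Convolutions are "same"-padded, implemented as im2col + GEMM; weights
// arrive as a (k*k*Cin) x Cout matrix whose row order matches the
// column-major reshape of a (k, k, Cin, Cout) R array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// gather patches of x (H x W x C cube) into (k*k*C) x (H*W), zero padding
static void im2col_same(const arma::cube& x, int k, arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  cols.zeros(k * k * C, H * W);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = dh + k * (dw + k * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - p;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, p - dh);
          const int h1 = std::min(H, H + p - dh);
          const double* src = &x(0, iw, c);
          double* dst = cols.colptr(w * H) + r;  // stride k*k*C per pixel
          for (int h = h0; h < h1; ++h)
            dst[(size_t)h * cols.n_rows] = src[h + dh - p];
        }
      }
    }
  }
}

// scatter-add inverse of im2col_same
static void col2im_same(const arma::mat& cols, int k, arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = dh + k * (dw + k * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - p;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, p - dh);
          const int h1 = std::min(H, H + p - dh);
          double* dst = &x(0, iw, c);
          const double* src = cols.colptr(w * H) + r;
          for (int h = h0; h < h1; ++h)
            dst[h + dh - p] += src[(size_t)h * cols.n_rows];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix wmat,
                           NumericVector bias, int k) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int K = k * k * C, Cout = wmat.ncol();
  if (wmat.nrow() != K) stop("weight matrix rows != k*k*in_channels");
  arma::mat wm(wmat.begin(), K, Cout, false);
  arma::vec b(bias.begin(), Cout, false);
  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat cols;
  const size_t in_stride = (size_t)H * W * C, out_stride = (size_t)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    const arma::cube xc(const_cast<double*>(x.begin()) + n * in_stride,
                        H, W, C, false, true);
    im2col_same(xc, k, cols);
    arma::mat out(y.begin() + n * out_stride, (size_t)H * W, Cout, false, true);
    out = cols.t() * wm;
    out.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix wmat, NumericVector dy,
                  int k) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int K = k * k * C, Cout = wmat.ncol();
  arma::mat wm(wmat.begin(), K, Cout, false);
  int dH, dW, dC, dN;
  dims4(dy, dH, dW, dC, dN);
  if (dH != H || dW != W || dC != Cout || dN != N)
    stop("gradient dims do not match conv output dims");
  NumericVector dx = alloc4(H, W, C, N);
  arma::mat dwm(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols;
  const size_t in_stride = (size_t)H * W * C, out_stride = (size_t)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    const arma::cube xc(const_cast<double*>(x.begin()) + n * in_stride,
                        H, W, C, false, true);
    im2col_same(xc, k, cols);
    const arma::mat dyn(const_cast<double*>(dy.begin()) + n * out_stride,
                        (size_t)H * W, Cout, false, true);
    dwm += cols * dyn;
    db += arma::sum(dyn, 0).t();
    arma::mat dcols = wm * dyn.t();  // K x HW
    arma::cube dxc(dx.begin() + n * in_stride, H, W, C, false, true);
    col2im_same(dcols, k, dxc);
  }
  NumericMatrix dwm_out(K, Cout);
  std::copy(dwm.begin(), dwm.end(), dwm_out.begin());
  NumericVector db_out(Cout);
  std::copy(db.begin(), db.end(), db_out.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwm_out, _["db"] = db_out);
}

// 2x2 max pooling, stride 2; idx records the 0-based linear argmax position
// in the input array so the backward pass is an exact scatter
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max_pool input height/width must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* px = x.begin();
  double* py = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t best = i00;
          double v = px[i00];
          const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int t = 0; t < 3; ++t)
            if (px[cand[t]] > v) { v = px[cand[t]]; best = cand[t]; }
          py[o] = v;
          idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector in_dim) {
  NumericVector dx = alloc4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  const int n = dy.size();
  for (int i = 0; i < n; ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = px[bi + (size_t)w * H + h];
          double* d = py + bo + (size_t)(2 * w) * Ho + 2 * h;
          d[0] = v; d[1] = v; d[Ho] = v; d[Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy) {
  int Ho, Wo, C, N;
  dims4(dy, Ho, Wo, C, N);
  if (Ho % 2 || Wo % 2) stop("upsample gradient dims must be even");
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx = alloc4(H, W, C, N);
  const double* py = dy.begin();
  double* px = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* s = py + bo + (size_t)(2 * w) * Ho + 2 * h;
          px[bi + (size_t)w * H + h] = s[0] + s[1] + s[Ho] + s[Ho + 1];
        }
    }
  return dx;
}
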