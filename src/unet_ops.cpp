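// Encoder-decoder CNN layer primitives: k x k "same" convolution (im2col +
// GEMM), 2x2 max-pooling, and 2x2-stride transposed convolution, each with
// its backward pass. Feature maps are (H, W, C) arrays; convolution weights
// are (k*k*Cin, Cout) matrices, transposed-convolution weights (Cin, 4*Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;

// column order: channel-major, then offset (dj, di); zero padding.
static mat im2col_same(const cube &x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = k / 2;
  mat out((size_t)H * W, (size_t)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di) {
        size_t col = (size_t)c * k * k + (size_t)(dj + r) * k + (di + r);
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            out((size_t)i + (size_t)H * j, col) = x(i + di, j + dj, c);
      }
  return out;
}

// scatter-add of a column matrix back onto the padded-image layout
static cube col2im_same(const mat &cols, int H, int W, int C, int k) {
  const int r = k / 2;
  cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di) {
        size_t col = (size_t)c * k * k + (size_t)(dj + r) * k + (di + r);
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            x(i + di, j + dj, c) += cols((size_t)i + (size_t)H * j, col);
      }
  return x;
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
arma::cube cpp_conv_fwd(const arma::cube &x, const arma::mat &w,
                        const arma::vec &b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat y = im2col_same(x, k) * w;           // (HW, Cout)
  y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(const arma::cube &x, const arma::mat &w,
                  const arma::cube &dy, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat dY((double *)dy.memptr(), (size_t)H * W, Cout, false, true);
  mat X = im2col_same(x, k);
  mat dW = X.t() * dY;
  vec db = arma::sum(dY, 0).t();
  mat dXcol = dY * w.t();
  cube dx = col2im_same(dXcol, H, W, Cin, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  arma::icube idx(h, w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int q = 0;
        for (int sj = 0; sj < 2; ++sj)
          for (int si = 0; si < 2; ++si) {
            double v = x(2 * i + si, 2 * j + sj, c);
            if (v > best) { best = v; q = sj * 2 + si; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = q;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
arma::cube cpp_maxpool_bwd(const arma::cube &dy, const arma::icube &idx) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        int q = idx(i, j, c);
        dx(2 * i + (q % 2), 2 * j + (q / 2), c) = dy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export(name = ".cpp_upconv_fwd")]]
arma::cube cpp_upconv_fwd(const arma::cube &x, const arma::mat &w,
                          const arma::vec &b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols / 4;
  mat X((double *)x.memptr(), (size_t)H * W, Cin, false, true);
  cube y(2 * H, 2 * W, Cout);
  for (int q = 0; q < 4; ++q) {
    int si = q % 2, sj = q / 2;
    mat Yq = X * w.cols((size_t)q * Cout, (size_t)(q + 1) * Cout - 1);
    Yq.each_row() += b.t();
    for (int c = 0; c < Cout; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          y(2 * i + si, 2 * j + sj, c) = Yq((size_t)i + (size_t)H * j, c);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upconv_bwd")]]
List cpp_upconv_bwd(const arma::cube &x, const arma::mat &w,
                    const arma::cube &dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat X((double *)x.memptr(), (size_t)H * W, Cin, false, true);
  mat dW(Cin, 4 * Cout, arma::fill::zeros);
  vec db(Cout, arma::fill::zeros);
  mat dX((size_t)H * W, Cin, arma::fill::zeros);
  mat dYq((size_t)H * W, Cout);
  for (int q = 0; q < 4; ++q) {
    int si = q % 2, sj = q / 2;
    for (int c = 0; c < Cout; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          dYq((size_t)i + (size_t)H * j, c) = dy(2 * i + si, 2 * j + sj, c);
    dW.cols((size_t)q * Cout, (size_t)(q + 1) * Cout - 1) = X.t() * dYq;
    db += arma::sum(dYq, 0).t();
    dX += dYq * w.cols((size_t)q * Cout, (size_t)(q + 1) * Cout - 1).t();
  }
  cube dx(H, W, Cin);
  std::memcpy(dx.memptr(), dX.memptr(), sizeof(double) * dX.n_elem);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
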