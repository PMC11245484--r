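// Compiled kernels for the 1D convolutional / recurrent layers.
// Tensors are arma::cube with dimensions (channels, time, batch).
// Convolutions are computed as cross-correlations (no kernel flip), the
// usual deep-learning convention, via im2col + GEMM across the whole batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube pad_cube(const cube& x, int pl, int pr) {
  if (pl == 0 && pr == 0) return x;
  cube xp(x.n_rows, x.n_cols + pl + pr, x.n_slices, fill::zeros);
  xp.cols(pl, pl + x.n_cols - 1) = x;
  return xp;
}

// im2col: (in_ch * k, t_out * batch)
static mat im2col(const cube& xp, int k, int stride, int t_out) {
  const int in_ch = xp.n_rows, batch = xp.n_slices;
  mat X(in_ch * k, (size_t)t_out * batch);
  for (int s = 0; s < batch; ++s) {
    const mat& xs = xp.slice(s);
    for (int t = 0; t < t_out; ++t) {
      // column-major copy of the window (in_ch x k)
      X.col((size_t)s * t_out + t) =
        vectorise(xs.cols(t * stride, t * stride + k - 1));
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::vec& b, int stride, int pl, int pr) {
  // x: (in_ch, T, batch); w: (in_ch, k, out_ch); b: (out_ch)
  const int k = w.n_cols, out_ch = w.n_slices, batch = x.n_slices;
  cube xp = pad_cube(x, pl, pr);
  const int t_out = (int(xp.n_cols) - k) / stride + 1;
  mat X = im2col(xp, k, stride, t_out);
  mat W2(out_ch, w.n_rows * k);
  for (int o = 0; o < out_ch; ++o) W2.row(o) = vectorise(w.slice(o)).t();
  mat Y = W2 * X;                 // (out_ch, t_out * batch)
  Y.each_col() += b;
  cube y(out_ch, t_out, batch);
  for (int s = 0; s < batch; ++s) {
    y.slice(s) = Y.cols((size_t)s * t_out, (size_t)(s + 1) * t_out - 1);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::cube& gy, int stride, int pl, int pr) {
  const int k = w.n_cols, out_ch = w.n_slices, batch = x.n_slices;
  const int in_ch = x.n_rows;
  cube xp = pad_cube(x, pl, pr);
  const int t_out = gy.n_cols;
  mat X = im2col(xp, k, stride, t_out);
  mat GY(out_ch, (size_t)t_out * batch);
  for (int s = 0; s < batch; ++s) {
    GY.cols((size_t)s * t_out, (size_t)(s + 1) * t_out - 1) = gy.slice(s);
  }
  mat W2(out_ch, (size_t)in_ch * k);
  for (int o = 0; o < out_ch; ++o) W2.row(o) = vectorise(w.slice(o)).t();
  mat GW2 = GY * X.t();           // (out_ch, in_ch * k)
  mat GX = W2.t() * GY;           // (in_ch * k, t_out * batch)
  cube gw(size(w));
  for (int o = 0; o < out_ch; ++o) {
    gw.slice(o) = reshape(GW2.row(o).t(), in_ch, k);
  }
  vec gb = sum(GY, 1);
  // scatter-add columns back into the padded input gradient
  cube gxp(size(xp), fill::zeros);
  for (int s = 0; s < batch; ++s) {
    mat& gxs = gxp.slice(s);
    for (int t = 0; t < t_out; ++t) {
      gxs.cols(t * stride, t * stride + k - 1) +=
        reshape(GX.col((size_t)s * t_out + t), in_ch, k);
    }
  }
  cube gx = gxp.cols(pl, pl + x.n_cols - 1);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube dwconv1d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b, int stride, int pl, int pr) {
  // depthwise: w is (k, ch), each channel convolved with its own filter
  const int k = w.n_rows, ch = w.n_cols, batch = x.n_slices;
  cube xp = pad_cube(x, pl, pr);
  const int t_out = (int(xp.n_cols) - k) / stride + 1;
  cube y(ch, t_out, batch);
  for (int s = 0; s < batch; ++s) {
    const mat& xs = xp.slice(s);
    mat& ys = y.slice(s);
    for (int t = 0; t < t_out; ++t) {
      const int p = t * stride;
      for (int c = 0; c < ch; ++c) {
        double acc = b(c);
        for (int j = 0; j < k; ++j) acc += xs(c, p + j) * w(j, c);
        ys(c, t) = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List dwconv1d_bwd_cpp(const arma::cube& x, const arma::mat& w,
                            const arma::cube& gy, int stride, int pl, int pr) {
  const int k = w.n_rows, ch = w.n_cols, batch = x.n_slices;
  cube xp = pad_cube(x, pl, pr);
  cube gxp(size(xp), fill::zeros);
  mat gw(size(w), fill::zeros);
  vec gb(ch, fill::zeros);
  const int t_out = gy.n_cols;
  for (int s = 0; s < batch; ++s) {
    const mat& xs = xp.slice(s);
    mat& gxs = gxp.slice(s);
    const mat& gys = gy.slice(s);
    for (int t = 0; t < t_out; ++t) {
      const int p = t * stride;
      for (int c = 0; c < ch; ++c) {
        const double g = gys(c, t);
        if (g == 0.0) continue;
        gb(c) += g;
        for (int j = 0; j < k; ++j) {
          gw(j, c) += g * xs(c, p + j);
          gxs(c, p + j) += g * w(j, c);
        }
      }
    }
  }
  cube gx = gxp.cols(pl, pl + x.n_cols - 1);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// LSTM kernels use the time-sliced layout (features, batch, time) so each
// step is whole-slice GEMM work; the R wrapper permutes to and from the
// (features, time, batch) convention used by the other layers.

// [[Rcpp::export]]
Rcpp::List lstm_fwd_cpp(const arma::cube& x, const arma::mat& wx,
                        const arma::mat& wh, const arma::vec& b) {
  // x: (in, batch, T); wx: (4H, in); wh: (4H, H); gate order i, f, g, o
  const int batch = x.n_cols, T = x.n_slices;
  const int H = wh.n_cols;
  cube h(H, batch, T), cst(H, batch, T), gates(4 * H, batch, T);
  mat hprev(H, batch, fill::zeros), cprev(H, batch, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat z = wx * x.slice(t) + wh * hprev;
    z.each_col() += b;
    mat i = 1.0 / (1.0 + exp(-z.rows(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-z.rows(H, 2 * H - 1)));
    mat g = tanh(z.rows(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-z.rows(3 * H, 4 * H - 1)));
    mat c = f % cprev + i % g;
    mat ht = o % tanh(c);
    gates.slice(t) = join_cols(i, f, g, o);
    cst.slice(t) = c;
    h.slice(t) = ht;
    hprev = ht; cprev = c;
  }
  return Rcpp::List::create(Rcpp::Named("h") = h,
                            Rcpp::Named("c") = cst,
                            Rcpp::Named("gates") = gates);
}

// [[Rcpp::export]]
Rcpp::List lstm_bwd_cpp(const arma::cube& x, const arma::mat& wx,
                        const arma::mat& wh, const arma::cube& h,
                        const arma::cube& cst, const arma::cube& gates,
                        const arma::cube& gh) {
  // all cubes in the (features, batch, time) layout
  const int batch = x.n_cols, T = x.n_slices;
  const int H = wh.n_cols;
  cube gx(size(x), fill::zeros);
  mat gwx(size(wx), fill::zeros), gwh(size(wh), fill::zeros);
  vec gb(4 * H, fill::zeros);
  mat dh_next(H, batch, fill::zeros), dc_next(H, batch, fill::zeros);
  const mat zerosHB(H, batch, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const mat& gt = gates.slice(t);
    const mat i = gt.rows(0, H - 1);
    const mat f = gt.rows(H, 2 * H - 1);
    const mat g = gt.rows(2 * H, 3 * H - 1);
    const mat o = gt.rows(3 * H, 4 * H - 1);
    const mat& c = cst.slice(t);
    const mat& cprev = (t > 0) ? cst.slice(t - 1) : zerosHB;
    const mat& hprev = (t > 0) ? h.slice(t - 1) : zerosHB;
    mat tc = tanh(c);
    mat dh = gh.slice(t) + dh_next;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat di = dc % g % i % (1.0 - i);
    mat df = dc % cprev % f % (1.0 - f);
    mat dg = dc % i % (1.0 - g % g);
    mat do_ = dh % tc % o % (1.0 - o);
    mat dz = join_cols(di, df, dg, do_);
    gwx += dz * x.slice(t).t();
    gwh += dz * hprev.t();
    gb += sum(dz, 1);
    gx.slice(t) = wx.t() * dz;
    dh_next = wh.t() * dz;
    dc_next = dc % f;
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gwx") = gwx,
                            Rcpp::Named("gwh") = gwh,
                            Rcpp::Named("gb") = gb);
}
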