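// Numerical kernels: GEMM-based 2D convolution (forward/backward),
// 2x2 max pooling, 2x2 stride-2 transposed convolution and binary
// connected-component labelling. Feature maps are arma::cube with
// dimensions (H, W, C); convolution weights are (k*k*Cin) x Cout
// matrices whose row index is c*k*k + di*k + dj for kernel offset
// (di, dj) and input channel c. Stride is 1 with "same" padding
// (pad = (k-1)/2), which is all the architecture needs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(H * (size_t)W, (size_t)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int idx = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H - 1, H - 1 + pad - di);
          if (i0 > i1) continue;
          // output pixel p = i + j*H pulls x(i + di - pad, sj, c)
          col(span(j * H + i0, j * H + i1), span(idx, idx)) =
            x.slice(c)(span(i0 + di - pad, i1 + di - pad), span(sj, sj));
        }
      }
    }
  }
  return col;
}

static void col2im_add(cube& gx, const mat& gcol, int k, int pad) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int idx = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H - 1, H - 1 + pad - di);
          if (i0 > i1) continue;
          gx.slice(c)(span(i0 + di - pad, i1 + di - pad), span(sj, sj)) +=
            gcol(span(j * H + i0, j * H + i1), span(idx, idx));
        }
      }
    }
  }
}

// Forward pass; optionally returns the im2col matrix for reuse in the
// backward pass (costs memory, saves rebuilding it).
// [[Rcpp::export]]
Rcpp::List conv2d_fw_full(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int pad,
                          bool keep_col) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  mat col = im2col(x, k, pad);
  mat y = col * W;
  y.each_row() += b.t();
  cube out(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.col(c), H, Wd);
  if (keep_col)
    return Rcpp::List::create(Rcpp::Named("y") = out,
                              Rcpp::Named("col") = col);
  return Rcpp::List::create(Rcpp::Named("y") = out);
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k, int pad) {
  Rcpp::List r = conv2d_fw_full(x, W, b, k, pad, false);
  return Rcpp::as<arma::cube>(r["y"]);
}

// Backward pass with a cached im2col matrix.
// [[Rcpp::export]]
Rcpp::List conv2d_bw_col(const arma::mat& col, const arma::mat& W,
                         const arma::cube& gy, int k, int pad, int Cin) {
  const int H = gy.n_rows, Wd = gy.n_cols;
  const int Cout = gy.n_slices;
  mat gy_mat(H * (size_t)Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    gy_mat.col(c) = vectorise(gy.slice(c));
  mat gW = col.t() * gy_mat;
  vec gb = sum(gy_mat, 0).t();
  mat gcol = gy_mat * W.t();
  cube gx(H, Wd, Cin, fill::zeros);
  col2im_add(gx, gcol, k, pad);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& W,
                     const arma::cube& gy, int k, int pad) {
  return conv2d_bw_col(im2col(x, k, pad), W, gy, k, pad, x.n_slices);
}

// 2x2 max pooling, stride 2; idx records the argmax offset (0..3;
// row offset = idx %% 2, column offset = idx %/% 2).
// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector idx(Ho * (size_t)Wo * C);
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c); int bi = 0;
        const double v1 = x(2 * i + 1, 2 * j, c);
        const double v2 = x(2 * i, 2 * j + 1, c);
        const double v3 = x(2 * i + 1, 2 * j + 1, c);
        if (v1 > best) { best = v1; bi = 1; }
        if (v2 > best) { best = v2; bi = 2; }
        if (v3 > best) { best = v3; bi = 3; }
        y(i, j, c) = best;
        ip[(size_t)c * Ho * Wo + (size_t)j * Ho + i] = bi;
      }
  idx.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const Rcpp::IntegerVector& idx, const arma::cube& gy) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(2 * Ho, 2 * Wo, C, fill::zeros);
  const int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int bi = ip[(size_t)c * Ho * Wo + (size_t)j * Ho + i];
        gx(2 * i + bi % 2, 2 * j + bi / 2, c) = gy(i, j, c);
      }
  return gx;
}

// Transposed 2x2 stride-2 convolution. Weight rows are ordered
// (a*2 + b)*Cin + c for output offset (a, b) within each 2x2 block.
// [[Rcpp::export]]
arma::cube upconv2_fw(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  mat xmat(H * (size_t)Wd, Cin);
  for (int c = 0; c < Cin; ++c) xmat.col(c) = vectorise(x.slice(c));
  cube y(2 * H, 2 * Wd, Cout);
  for (int ab = 0; ab < 4; ++ab) {
    const int a = ab / 2, bb = ab % 2;
    mat yab = xmat * W.rows(ab * Cin, ab * Cin + Cin - 1);
    yab.each_row() += b.t();
    for (int c = 0; c < Cout; ++c)
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          y(2 * i + a, 2 * j + bb, c) = yab(j * H + i, c);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List upconv2_bw(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat xmat(H * (size_t)Wd, Cin);
  for (int c = 0; c < Cin; ++c) xmat.col(c) = vectorise(x.slice(c));
  mat gW(4 * Cin, Cout, fill::zeros);
  vec gb(Cout, fill::zeros);
  mat gxmat(H * (size_t)Wd, Cin, fill::zeros);
  mat gyab(H * (size_t)Wd, Cout);
  for (int ab = 0; ab < 4; ++ab) {
    const int a = ab / 2, bb = ab % 2;
    for (int c = 0; c < Cout; ++c)
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          gyab(j * H + i, c) = gy(2 * i + a, 2 * j + bb, c);
    gW.rows(ab * Cin, ab * Cin + Cin - 1) = xmat.t() * gyab;
    gb += sum(gyab, 0).t();
    gxmat += gyab * W.rows(ab * Cin, ab * Cin + Cin - 1).t();
  }
  cube gx(H, Wd, Cin);
  for (int c = 0; c < Cin; ++c)
    gx.slice(c) = reshape(gxmat.col(c), H, Wd);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Batch-norm over the spatial plane (batch of one): returns channel
// stats, the normalized map and the affine output in one pass.
// [[Rcpp::export]]
Rcpp::List bn_fw(const arma::mat& m, const arma::vec& gamma,
                 const arma::vec& beta, const arma::vec& mu,
                 const arma::vec& invstd) {
  const int n = m.n_rows, C = m.n_cols;
  mat xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    xhat.col(c) = (m.col(c) - mu(c)) * invstd(c);
    y.col(c) = xhat.col(c) * gamma(c) + beta(c);
  }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("y") = y);
}

// [[Rcpp::export]]
Rcpp::List bn_bw(const arma::mat& gm, const arma::mat& xhat,
                 const arma::vec& gamma, const arma::vec& invstd,
                 bool training) {
  const int n = gm.n_rows, C = gm.n_cols;
  mat gx(n, C);
  vec gbeta(C), ggamma(C);
  for (int c = 0; c < C; ++c) {
    gbeta(c) = accu(gm.col(c));
    ggamma(c) = dot(gm.col(c), xhat.col(c));
    if (training) {
      gx.col(c) = (gm.col(c) * gamma(c) -
                   (gamma(c) * gbeta(c)) / n -
                   xhat.col(c) * (gamma(c) * ggamma(c) / n)) * invstd(c);
    } else {
      gx.col(c) = gm.col(c) * gamma(c) * invstd(c);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gbeta") = gbeta,
                            Rcpp::Named("ggamma") = ggamma);
}

// ReLU forward / backward.
// [[Rcpp::export]]
arma::cube relu_fw(const arma::cube& x) {
  cube y = x;
  y.for_each([](double& v) { if (v < 0) v = 0; });
  return y;
}

// [[Rcpp::export]]
arma::cube relu_bw(const arma::cube& x, const arma::cube& g) {
  cube gx = g;
  const double* xp = x.memptr();
  double* gp = gx.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) if (xp[i] <= 0) gp[i] = 0;
  return gx;
}

// Connected-component labelling of a binary matrix (4- or
// 8-connectivity). Returns 0 for background, 1..n for components.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cc_label(const Rcpp::IntegerMatrix& mask,
                             int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  const int n_nb = (connectivity == 8) ? 8 : 4;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int d = 0; d < n_nb; ++d) {
          const int ni = p.first + di[d], nj = p.second + dj[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(std::make_pair(ni, nj));
          }
        }
      }
    }
  return lab;
}
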