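// Low-level tensor primitives for the compact UNet.
//
// Batched feature maps are arma::cube of shape (H, W, C * B) with image-major
// slice layout: slice index = (b * C) + c for image b in [0, B) and channel c
// in [0, C).  Convolution weights are (9 * Cin) x Cout matrices with row index
// (ky * 3 + kx) * Cin + ci; up-convolution weights are Cin x (4 * Cout) with
// column index q * Cout + co, q = dr * 2 + dc.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col over the whole batch: X is (H*W*nimg) x (9*cin); row block bi*H*W
// holds image bi. Column (ky*3+kx)*cin+ci holds the (ky-1, kx-1)-shifted
// channel ci, zero-padded. Column segments are contiguous, so shifts reduce
// to memcpy of column strips.
static void im2col3_batch(const arma::cube& x, int nimg, int cin, arma::mat& X) {
  const int H = x.n_rows, W = x.n_cols, HW = H * W;
  X.zeros();
  for (int bi = 0; bi < nimg; ++bi) {
    for (int ky = 0; ky < 3; ++ky) {
      const int r0 = std::max(0, 1 - ky), r1 = std::min(H, H + 1 - ky);
      const int len = r1 - r0;
      for (int kx = 0; kx < 3; ++kx) {
        for (int ci = 0; ci < cin; ++ci) {
          const double* src = x.slice(bi * cin + ci).memptr();
          double* dst = X.colptr((ky * 3 + kx) * cin + ci) + bi * HW;
          for (int c = 0; c < W; ++c) {
            const int c2 = c + kx - 1;
            if (c2 < 0 || c2 >= W) continue;
            std::memcpy(dst + c * H + r0, src + c2 * H + r0 + ky - 1,
                        len * sizeof(double));
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3x3Fw")]]
arma::cube conv3x3_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int nimg) {
  const int H = x.n_rows, W = x.n_cols, HW = H * W;
  const int cin = x.n_slices / nimg;
  const int cout = w.n_cols;
  arma::mat X(HW * nimg, 9 * cin);
  im2col3_batch(x, nimg, cin, X);
  arma::mat Y = X * w;
  arma::cube y(H, W, cout * nimg);
  for (int bi = 0; bi < nimg; ++bi)
    for (int co = 0; co < cout; ++co) {
      double* dst = y.slice(bi * cout + co).memptr();
      const double* src = Y.colptr(co) + bi * HW;
      const double bias = b(co);
      for (int i = 0; i < HW; ++i) dst[i] = src[i] + bias;
    }
  return y;
}

// [[Rcpp::export(name = ".conv3x3Bw")]]
List conv3x3_bw(const arma::cube& x, const arma::mat& w,
                const arma::cube& gy, int nimg) {
  const int H = x.n_rows, W = x.n_cols, HW = H * W;
  const int cin = x.n_slices / nimg;
  const int cout = w.n_cols;
  arma::mat X(HW * nimg, 9 * cin);
  im2col3_batch(x, nimg, cin, X);
  arma::mat G(HW * nimg, cout);
  for (int bi = 0; bi < nimg; ++bi)
    for (int co = 0; co < cout; ++co)
      std::memcpy(G.colptr(co) + bi * HW,
                  gy.slice(bi * cout + co).memptr(), HW * sizeof(double));
  arma::mat gw = X.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat Gc = G * w.t();  // (H*W*nimg) x (9*cin)
  arma::cube gx(H, W, x.n_slices, arma::fill::zeros);
  for (int bi = 0; bi < nimg; ++bi) {
    for (int ky = 0; ky < 3; ++ky) {
      const int r0 = std::max(0, 1 - ky), r1 = std::min(H, H + 1 - ky);
      const int len = r1 - r0;
      for (int kx = 0; kx < 3; ++kx) {
        for (int ci = 0; ci < cin; ++ci) {
          double* dst = gx.slice(bi * cin + ci).memptr();
          const double* src = Gc.colptr((ky * 3 + kx) * cin + ci) + bi * HW;
          for (int c = 0; c < W; ++c) {
            const int c2 = c + kx - 1;
            if (c2 < 0 || c2 >= W) continue;
            double* d = dst + c2 * H + r0 + ky - 1;
            const double* s = src + c * H + r0;
            for (int r = 0; r < len; ++r) d[r] += s[r];
          }
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool2Fw")]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, S);
  arma::icube idx(Ho, Wo, S);  // argmax position dr * 2 + dc within the 2x2 window
  for (int s = 0; s < S; ++s) {
    const arma::mat& sl = x.slice(s);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = sl(2 * r, 2 * c);
        int bi = 0;
        for (int q = 1; q < 4; ++q) {
          const double v = sl(2 * r + q / 2, 2 * c + q % 2);
          if (v > best) { best = v; bi = q; }
        }
        y(r, c, s) = best;
        idx(r, c, s) = bi;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2Bw")]]
arma::cube maxpool2_bw(const arma::icube& idx, const arma::cube& gy) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, S = gy.n_slices;
  arma::cube gx(2 * Ho, 2 * Wo, S, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int q = idx(r, c, s);
        gx(2 * r + q / 2, 2 * c + q % 2, s) = gy(r, c, s);
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".upconv2Fw")]]
arma::cube upconv2_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int nimg) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices / nimg;
  const int cout = w.n_cols / 4;
  arma::cube y(2 * H, 2 * W, cout * nimg);
  for (int bi = 0; bi < nimg; ++bi) {
    arma::mat X(H * W, cin);
    for (int ci = 0; ci < cin; ++ci)
      X.col(ci) = arma::vectorise(x.slice(bi * cin + ci));
    arma::mat Y = X * w;  // (H*W) x (4*cout)
    for (int co = 0; co < cout; ++co) {
      arma::mat& sl = y.slice(bi * cout + co);
      for (int q = 0; q < 4; ++q) {
        const int dr = q / 2, dc = q % 2;
        arma::mat blk = arma::reshape(Y.col(q * cout + co), H, W);
        for (int c = 0; c < W; ++c)
          for (int r = 0; r < H; ++r)
            sl(2 * r + dr, 2 * c + dc) = blk(r, c) + b(co);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upconv2Bw")]]
List upconv2_bw(const arma::cube& x, const arma::mat& w,
                const arma::cube& gy, int nimg) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices / nimg;
  const int cout = w.n_cols / 4;
  arma::cube gx(H, W, x.n_slices);
  arma::mat gw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  for (int bi = 0; bi < nimg; ++bi) {
    arma::mat X(H * W, cin);
    for (int ci = 0; ci < cin; ++ci)
      X.col(ci) = arma::vectorise(x.slice(bi * cin + ci));
    arma::mat G(H * W, 4 * cout);
    for (int co = 0; co < cout; ++co) {
      const arma::mat& sl = gy.slice(bi * cout + co);
      for (int q = 0; q < 4; ++q) {
        const int dr = q / 2, dc = q % 2;
        arma::mat blk(H, W);
        for (int c = 0; c < W; ++c)
          for (int r = 0; r < H; ++r)
            blk(r, c) = sl(2 * r + dr, 2 * c + dc);
        G.col(q * cout + co) = arma::vectorise(blk);
        gb(co) += arma::accu(blk);
      }
    }
    gw += X.t() * G;
    arma::mat GX = G * w.t();  // (H*W) x cin
    for (int ci = 0; ci < cin; ++ci)
      gx.slice(bi * cin + ci) = arma::reshape(GX.col(ci), H, W);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// 8-connectivity connected-component labeling of a binary mask.
// [[Rcpp::export(name = ".labelComponents8")]]
IntegerMatrix label_components8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int r2 = pr + dr, c2 = pc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * H);
            }
          }
        }
      }
    }
  }
  return lab;
}
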