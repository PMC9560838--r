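// Minimal CPU convnet primitives for the 2-D UNet: im2col-based 3x3/1x1
// convolution with same-padding, 2x2 max pooling, nearest-neighbour 2x
// upsampling, and 8-connectivity component labeling. Tensors are arma::cube
// with layout (H, W, C); batching is handled by the R caller.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cols matrix is (Cin*k*k, H*W); column index = r*W? No: column index j
// corresponds to output pixel (row i, col jj) with j = i + H*jj (column-major
// over the HxW grid, matching arma cube slice layout).
static arma::mat im2col(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        const int rowidx = c * k * k + dr * k + dc;
        for (int jj = 0; jj < W; ++jj) {
          const int sc = jj + dc - pad;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int sr = i + dr - pad;
            if (sr < 0 || sr >= H) continue;
            cols(rowidx, i + H * jj) = xs(sr, sc);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int k, int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xs = x.slice(c);
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        const int rowidx = c * k * k + dr * k + dc;
        for (int jj = 0; jj < W; ++jj) {
          const int sc = jj + dc - pad;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int sr = i + dr - pad;
            if (sr < 0 || sr >= H) continue;
            xs(sr, sc) += cols(rowidx, i + H * jj);
          }
        }
      }
    }
  }
  return x;
}

// y = conv(x, W) + b; W is (Cout, Cin*k*k), output (H, W, Cout).
// [[Rcpp::export(rng = false)]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat cols = im2col(x, k, pad);
  arma::mat ymat = w * cols;           // (Cout, H*W)
  ymat.each_col() += b;
  arma::cube y(H, W, ymat.n_rows);
  for (arma::uword c = 0; c < ymat.n_rows; ++c) {
    y.slice(c) = arma::reshape(ymat.row(c), H, W);
  }
  return y;
}

// Gradients of the same convolution. gy has shape (H, W, Cout).
// [[Rcpp::export(rng = false)]]
List conv2d_backward(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gymat(Cout, H * W);
  for (int c = 0; c < Cout; ++c) {
    gymat.row(c) = arma::vectorise(gy.slice(c)).t();
  }
  arma::mat cols = im2col(x, k, pad);
  arma::mat gw = gymat * cols.t();
  arma::vec gb = arma::sum(gymat, 1);
  arma::mat gcols = w.t() * gymat;
  arma::cube gx = col2im(gcols, H, W, C, k, pad);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even (caller pads).
// idx stores, per output element, the linear index into the input slice.
// [[Rcpp::export(rng = false)]]
List maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::cube idx(Ho, Wo, C);   // linear input index per output, as double
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = xs(2 * i, 2 * j);
        double bi = 2 * i + H * (2 * j);
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = xs(2 * i + di, 2 * j + dj);
            if (v > best) {
              best = v;
              bi = (2 * i + di) + H * (2 * j + dj);
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
arma::cube maxpool2_backward(const arma::cube& gy, const arma::cube& idx,
                             int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& gs = gx.slice(c);
    for (arma::uword j = 0; j < gy.n_cols; ++j) {
      for (arma::uword i = 0; i < gy.n_rows; ++i) {
        gs(static_cast<arma::uword>(idx(i, j, c))) += gy(i, j, c);
      }
    }
  }
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(rng = false)]]
arma::cube upsample2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
arma::cube upsample2_backward(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return gx;
}

// 8-connectivity component labeling of a binary matrix (nonzero = fg).
// Labels are assigned in scan order (column-major), so the component that
// contains the topmost-leftmost foreground pixel gets label 1: deterministic.
// [[Rcpp::export(rng = false)]]
arma::imat label_components8(const arma::mat& mask) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
        }
      }
    }
  }
  return lab;
}
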