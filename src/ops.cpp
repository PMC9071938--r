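// Low-level numerical primitives: same-padded 2D convolution (im2col + BLAS)
// with analytic backward passes, 26-connectivity 3D component labelling, and
// a brute-force 3D median filter. All array layouts are R column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for an H x W x C input and k x k kernel with same (zero) padding.
// Output: (H*W) x (k*k*C), row r = flattened receptive field of pixel r.
static arma::mat im2col_same(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = k / 2;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - half;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - half;
            if (si < 0 || si >= H) continue;
            cols(j * H + i, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add a (H*W) x (k*k*C) matrix back to H x W x C.
static arma::cube col2im_same(const arma::mat& cols, int H, int W, int C, int k) {
  const int half = k / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - half;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - half;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += cols(j * H + i, col);
          }
        }
      }
    }
  }
  return x;
}

// Forward convolution: x (H x W x Cin), w ((k*k*Cin) x Cout), b (Cout).
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y = im2col_same(x, k) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// Backward convolution: gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gym(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  arma::mat cols = im2col_same(x, k);
  arma::mat gw = cols.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::cube gx = col2im_same(gym * w.t(), H, W, Cin, k);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// 3D connected-component labelling of a logical mask, 26-neighbourhood.
// Returns an integer array of labels (0 = background), labels 1..n.
// [[Rcpp::export]]
IntegerVector label_components_3d(const LogicalVector& mask,
                                  const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      const int i = v % nx, j = (v / nx) % ny, kk = v / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        const int zk = kk + dk; if (zk < 0 || zk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int yj = j + dj; if (yj < 0 || yj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int xi = i + di; if (xi < 0 || xi >= nx) continue;
            const R_xlen_t u = xi + (R_xlen_t)nx * (yj + (R_xlen_t)ny * zk);
            if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 3D median filter with box half-widths (rx, ry, rz) in voxels; edges use
// the truncated neighbourhood.
// [[Rcpp::export]]
NumericVector median_filter_3d(const NumericVector& vol,
                               const IntegerVector& dims,
                               int rx, int ry, int rz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> buf;
  buf.reserve((2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1));
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = std::max(0, k - rz); dk <= std::min(nz - 1, k + rz); ++dk)
          for (int dj = std::max(0, j - ry); dj <= std::min(ny - 1, j + ry); ++dj)
            for (int di = std::max(0, i - rx); di <= std::min(nx - 1, i + rx); ++di)
              buf.push_back(vol[di + (R_xlen_t)nx * (dj + (R_xlen_t)ny * dk)]);
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = med;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
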