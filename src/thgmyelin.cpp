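#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 26-connected component labeling of a 3D binary volume stored column-major
// with dimensions (ny, nx, nz). Iterative flood fill; labels start at 1.
// [[Rcpp::export]]
IntegerVector cc3d_label(IntegerVector mask, int ny, int nx, int nz) {
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sy = 1, sx = ny, sz = (R_xlen_t)ny * nx;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / sz);
      R_xlen_t r = v % sz;
      int x = (int)(r / sx);
      int y = (int)(r % sx);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dy && !dx && !dz) continue;
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            R_xlen_t w = yy * sy + (R_xlen_t)xx * sx + (R_xlen_t)zz * sz;
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Separable 2D convolution with centred odd-length kernels and replicated
// edges: convolve columns with ky (along y), then rows with kx (along x).
// [[Rcpp::export]]
NumericMatrix sep_conv2(NumericMatrix m, NumericVector ky,
                        NumericVector kx) {
  const int ny = m.nrow(), nx = m.ncol();
  const int hy = ((int)ky.size() - 1) / 2;
  const int hx = ((int)kx.size() - 1) / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0;
      for (int j = -hy; j <= hy; ++j) {
        int yy = y + j;
        if (yy < 0) yy = 0;
        if (yy >= ny) yy = ny - 1;
        acc += ky[j + hy] * m(yy, x);
      }
      tmp(y, x) = acc;
    }
  }
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double acc = 0;
      for (int j = -hx; j <= hx; ++j) {
        int xx = x + j;
        if (xx < 0) xx = 0;
        if (xx >= nx) xx = nx - 1;
        acc += kx[j + hx] * tmp(y, xx);
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Batch inference over a flattened probability forest (exported from the
// trainer's trees): per row, walk each tree (numeric split: value <= splitval
// goes left) and average the terminal-node class probability.
// left/right/var are node x tree matrices (-1 marks terminal), val holds
// split values and prob the terminal probability of the target class.
// [[Rcpp::export]]
NumericVector forest_predict_prob(NumericMatrix X, IntegerMatrix left,
                                  IntegerMatrix right, IntegerMatrix var,
                                  NumericMatrix val, NumericMatrix prob) {
  const int n = X.nrow();
  const int T = left.ncol();
  NumericVector out(n);
  const double *xp = X.begin();
  const int nr = n;
  for (int t = 0; t < T; ++t) {
    const int *L = &left(0, t);
    const int *R = &right(0, t);
    const int *V = &var(0, t);
    const double *S = &val(0, t);
    const double *P = &prob(0, t);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (L[node] >= 0) {
        node = (xp[i + (R_xlen_t)V[node] * nr] <= S[node]) ? L[node]
                                                           : R[node];
      }
      out[i] += P[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// 2D median filter over the disk {dx^2 + dy^2 <= r^2}, reflected borders.
// [[Rcpp::export]]
NumericMatrix median_disk2d(NumericMatrix m, int radius) {
  const int ny = m.nrow(), nx = m.ncol();
  std::vector<int> offy, offx;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) {
        offy.push_back(dy);
        offx.push_back(dx);
      }
  const int k = (int)offy.size();
  NumericMatrix out(ny, nx);
  std::vector<double> buf(k);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int j = 0; j < k; ++j) {
        int yy = y + offy[j], xx = x + offx[j];
        if (yy < 0) yy = -yy - 1;               // reflect
        if (yy >= ny) yy = 2 * ny - yy - 1;
        if (xx < 0) xx = -xx - 1;
        if (xx >= nx) xx = 2 * nx - xx - 1;
        buf[j] = m(yy, xx);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (!(k & 1)) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = 0.5 * (med + lo);
      }
      out(y, x) = med;
    }
  }
  return out;
}
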