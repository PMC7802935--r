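// Low-level numerical kernels: im2col-based 2D convolution (same padding,
// stride 1) with analytic gradients, 2x2 max pooling, 2x2/stride-2 transposed
// convolution, Zhang-Suen thinning and 4-connected labelling.
//
// Array conventions (match R's column-major layout):
//   activations  x[H, W, C, N]   (height, width, channels, batch)
//   conv weights w[k, k, C, F]   (kernel row, kernel col, in-ch, out-ch)
//   upconv weights w[2, 2, C, F]
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static NumericVector arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static IntegerVector iarr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::uvec dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return arma::uvec{(unsigned)d[0], (unsigned)d[1], (unsigned)d[2], (unsigned)d[3]};
}

// Gather k x k x C patches around every pixel (zero padding) into a
// (k*k*C) x (H*W) matrix; pixel (i,j) maps to column j*H + i.
static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& cols) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) cols((unsigned)r, (unsigned)(j * H + i)) = 0.0;
            continue;
          }
          const double* src = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            cols((unsigned)r, (unsigned)(j * H + i)) =
              (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
}

// Scatter-add the transpose of im2col: cols (k*k*C) x (H*W) back into x.
static void col2im(const arma::mat& cols, int H, int W, int C, int k,
                   double* x) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si >= 0 && si < H)
              dst[si] += cols((unsigned)r, (unsigned)(j * H + i));
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], F = dw[3];
  if ((int)dw[2] != C) stop("channel mismatch between input and weights");
  NumericVector y = arr4(H, W, F, N);
  arma::mat Wm(w.begin(), (size_t)k * k * C, F, false, true);
  arma::mat cols((size_t)k * k * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat out = Wm.t() * cols; // F x (H*W)
    double* yp = y.begin() + (size_t)n * H * W * F;
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      for (int p = 0; p < H * W; ++p)
        yp[(size_t)f * H * W + p] = out((unsigned)f, (unsigned)p) + bf;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dx_ = dims4(x), dw_ = dims4(w);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], F = dw_[3];
  NumericVector dx = arr4(H, W, C, N);
  NumericVector dw = arr4(k, k, C, F);
  NumericVector db(F);
  arma::mat Wm(w.begin(), (size_t)k * k * C, F, false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * C, F, false, true);
  arma::vec dbv(db.begin(), F, false, true);
  arma::mat cols((size_t)k * k * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * H * W * F,
                  (size_t)H * W, F, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    dWm += cols * dYm;                       // (kkC x HW) * (HW x F)
    dbv += arma::sum(dYm, 0).t();
    arma::mat dcols = Wm * dYm.t();          // kkC x HW
    col2im(dcols, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax indices
// (0-based within each H*W channel plane) for the backward pass.
// [[Rcpp::export(name = ".pool_fwd")]]
List pool_fwd(NumericVector x) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = arr4(Ho, Wo, C, N);
  IntegerVector idx = iarr4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int best = (2 * j) * H + 2 * i;
          double bv = xp[best];
          const int cand[3] = {(2 * j) * H + 2 * i + 1,
                               (2 * j + 1) * H + 2 * i,
                               (2 * j + 1) * H + 2 * i + 1};
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          yp[(size_t)j * Ho + i] = bv;
          ip[(size_t)j * Ho + i] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".pool_bwd")]]
NumericVector pool_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  arma::uvec d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = arr4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dxp = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int p = 0; p < Ho * Wo; ++p) dxp[ip[p]] += dyp[p];
    }
  return dx;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping):
// y[2i+a, 2j+b, f] = b[f] + sum_c x[i,j,c] * w[a,b,c,f]
// [[Rcpp::export(name = ".upconv_fwd")]]
NumericVector upconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3], F = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = arr4(Ho, Wo, F, N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      double* yp = y.begin() + ((size_t)n * F + f) * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p) yp[p] = b[f];
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
        const double* wp = w.begin() + ((size_t)f * C + c) * 4; // w[a,b,c,f]
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xp[(size_t)j * H + i];
            double* o = yp + (size_t)(2 * j) * Ho + 2 * i;
            o[0]      += v * wp[0];
            o[1]      += v * wp[1];
            o[Ho]     += v * wp[2];
            o[Ho + 1] += v * wp[3];
          }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".upconv_bwd")]]
List upconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dx_ = dims4(x), dw_ = dims4(w);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3], F = dw_[3];
  const int Ho = 2 * H;
  NumericVector dx = arr4(H, W, C, N);
  NumericVector dw = arr4(2, 2, C, F);
  NumericVector db(F);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double* dyp = dy.begin() + ((size_t)n * F + f) * Ho * 2 * W;
      for (int p = 0; p < Ho * 2 * W; ++p) db[f] += dyp[p];
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
        const double* wp = w.begin() + ((size_t)f * C + c) * 4;
        double* dwp = dw.begin() + ((size_t)f * C + c) * 4;
        double* dxp = dx.begin() + ((size_t)n * C + c) * H * W;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double* o = dyp + (size_t)(2 * j) * Ho + 2 * i;
            const double v = xp[(size_t)j * H + i];
            dwp[0] += v * o[0];  dwp[1] += v * o[1];
            dwp[2] += v * o[Ho]; dwp[3] += v * o[Ho + 1];
            dxp[(size_t)j * H + i] +=
              wp[0] * o[0] + wp[1] * o[1] + wp[2] * o[Ho] + wp[3] * o[Ho + 1];
          }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Zhang-Suen binary thinning to a 1-pixel-wide skeleton.
// [[Rcpp::export(name = ".thin_binary")]]
IntegerMatrix thin_binary(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m(clone(mask));
  auto at = [&](int i, int j) -> int {
    return (i < 0 || i >= H || j < 0 || j >= W) ? 0 : m(i, j);
  };
  bool changed = true;
  std::vector<std::pair<int,int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int i = 0; i < H; ++i)
        for (int j = 0; j < W; ++j) {
          if (!m(i, j)) continue;
          // neighbours p2..p9 clockwise from north
          int p[8] = {at(i-1,j), at(i-1,j+1), at(i,j+1), at(i+1,j+1),
                      at(i+1,j), at(i+1,j-1), at(i,j-1), at(i-1,j-1)};
          int B = 0, A = 0;
          for (int q = 0; q < 8; ++q) {
            B += p[q];
            if (!p[q] && p[(q + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.emplace_back(i, j);
        }
      for (auto& ij : kill) m(ij.first, ij.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

// 4-connected component labelling (BFS); labels are consecutive from 1.
// [[Rcpp::export(name = ".label4")]]
IntegerMatrix label4(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      stack.clear();
      stack.push_back(j0 * H + i0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % H, j = p / H;
        const int ni[4] = {i - 1, i + 1, i, i};
        const int nj[4] = {j, j, j - 1, j + 1};
        for (int q = 0; q < 4; ++q) {
          int a = ni[q], b = nj[q];
          if (a < 0 || a >= H || b < 0 || b >= W) continue;
          if (mask(a, b) && !lab(a, b)) {
            lab(a, b) = next;
            stack.push_back(b * H + a);
          }
        }
      }
    }
  return lab;
}
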