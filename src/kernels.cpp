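// Numerical kernels for the segmentation network and the Ising-MRF polish.
//
// Feature maps are stored as (B*H*W) x C matrices: sample b (0-based)
// occupies rows [b*H*W, (b+1)*H*W); within a sample, pixel (i, j)
// (0-based) sits at row i + j*H (column-major, matching R arrays).
// im2col uses 3x3 windows, zero padding 1; patch element k = (di+1) +
// 3*(dj+1) for offsets di, dj in {-1, 0, 1}; column c*9 + k of the output
// corresponds to input channel c, offset k (so a conv weight matrix is
// (9*C_in) x C_out with rows in the same order).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// copy a spatially shifted view of src (B*H*W x C) into dst, zero-filling
// out-of-bounds: dst(i, j) = src(i + di, j + dj) within each sample
static void shift_copy(const double* src, double* dst, int H, int W, int B,
                       int C, int di, int dj) {
  const R_xlen_t HW = (R_xlen_t)H * W, rows = (R_xlen_t)B * HW;
  std::fill(dst, dst + rows * C, 0.0);
  const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
  const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
  if (i0 >= i1 || j0 >= j1) return;
  for (int c = 0; c < C; ++c) {
    const double* sc = src + c * rows;
    double* dc = dst + c * rows;
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base = b * HW;
      for (int j = j0; j < j1; ++j) {
        const double* s = sc + base + (R_xlen_t)(j + dj) * H + (i0 + di);
        double* d = dc + base + (R_xlen_t)j * H + i0;
        std::copy(s, s + (i1 - i0), d);
      }
    }
  }
}

// gather kernel-offset k's Cin x Cout weight slice out of the (9*Cin) x
// Cout matrix whose rows are ordered c*9 + k
static void gather_wk(const double* Wm, double* Wk, int Cin, int Cout, int k) {
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      Wk[c + (R_xlen_t)co * Cin] = Wm[(R_xlen_t)c * 9 + k + (R_xlen_t)co * 9 * Cin];
}

// 3x3 same-padding convolution: Y = sum_k shift_k(X) * W_k + b
// [[Rcpp::export]]
NumericMatrix conv3x3_forward(const NumericMatrix& X, const NumericMatrix& Wm,
                              const NumericVector& b, int H, int W, int B) {
  const int Cin = X.ncol(), Cout = Wm.ncol();
  const int rows = B * H * W;
  NumericMatrix Y(rows, Cout);
  std::vector<double> S((R_xlen_t)rows * Cin), Wk((R_xlen_t)Cin * Cout);
  const double one = 1.0;
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1, dj = k / 3 - 1;
    shift_copy(REAL(X), S.data(), H, W, B, Cin, di, dj);
    gather_wk(REAL(Wm), Wk.data(), Cin, Cout, k);
    const double beta = (k == 0) ? 0.0 : 1.0;
    F77_CALL(dgemm)("N", "N", &rows, &Cout, &Cin, &one, S.data(), &rows,
                    Wk.data(), &Cin, &beta, REAL(Y), &rows FCONE FCONE);
  }
  for (int co = 0; co < Cout; ++co) {
    double* y = REAL(Y) + (R_xlen_t)co * rows;
    for (int r = 0; r < rows; ++r) y[r] += b[co];
  }
  return Y;
}

// gradients of the 3x3 convolution:
//   dX = sum_k shift_{-k}(dY) * W_k',  dW_k = shift_k(X)' * dY,
//   db = colSums(dY)
// [[Rcpp::export]]
List conv3x3_backward(const NumericMatrix& dY, const NumericMatrix& X,
                      const NumericMatrix& Wm, int H, int W, int B) {
  const int Cin = X.ncol(), Cout = dY.ncol();
  const int rows = B * H * W;
  NumericMatrix dX(rows, Cin), dW(9 * Cin, Cout);
  NumericVector db(Cout);
  std::vector<double> S((R_xlen_t)rows * std::max(Cin, Cout));
  std::vector<double> Wk((R_xlen_t)Cin * Cout), dWk((R_xlen_t)Cin * Cout);
  const double one = 1.0, zero = 0.0;
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1, dj = k / 3 - 1;
    // dX accumulation
    shift_copy(REAL(dY), S.data(), H, W, B, Cout, -di, -dj);
    gather_wk(REAL(Wm), Wk.data(), Cin, Cout, k);
    F77_CALL(dgemm)("N", "T", &rows, &Cin, &Cout, &one, S.data(), &rows,
                    Wk.data(), &Cin, &one, REAL(dX), &rows FCONE FCONE);
    // dW_k
    shift_copy(REAL(X), S.data(), H, W, B, Cin, di, dj);
    F77_CALL(dgemm)("T", "N", &Cin, &Cout, &rows, &one, S.data(), &rows,
                    REAL(dY), &rows, &zero, dWk.data(), &Cin FCONE FCONE);
    for (int co = 0; co < Cout; ++co)
      for (int c = 0; c < Cin; ++c)
        REAL(dW)[(R_xlen_t)c * 9 + k + (R_xlen_t)co * 9 * Cin] =
          dWk[c + (R_xlen_t)co * Cin];
  }
  for (int co = 0; co < Cout; ++co) {
    const double* y = REAL(dY) + (R_xlen_t)co * rows;
    double s = 0.0;
    for (int r = 0; r < rows; ++r) s += y[r];
    db[co] = s;
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericMatrix im2col3x3(const NumericMatrix& X, int H, int W, int B) {
  const int HW = H * W, C = X.ncol();
  NumericMatrix out(B * HW, 9 * C);
  for (int b = 0; b < B; ++b) {
    const int base = b * HW;
    for (int c = 0; c < C; ++c) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int k = (di + 1) + 3 * (dj + 1);
          const int col = c * 9 + k;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int is = i + di;
              if (is < 0 || is >= H) continue;
              out(base + i + j * H, col) = X(base + is + js * H, c);
            }
          }
        }
      }
    }
  }
  return out;
}

// transpose of im2col as a linear map: scatter-add gradient columns back
// [[Rcpp::export]]
NumericMatrix col2im3x3(const NumericMatrix& dCol, int H, int W, int B, int C) {
  const int HW = H * W;
  NumericMatrix dX(B * HW, C);
  for (int b = 0; b < B; ++b) {
    const int base = b * HW;
    for (int c = 0; c < C; ++c) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int col = c * 9 + (di + 1) + 3 * (dj + 1);
          for (int j = 0; j < W; ++j) {
            const int js = j + dj;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int is = i + di;
              if (is < 0 || is >= H) continue;
              dX(base + is + js * H, c) += dCol(base + i + j * H, col);
            }
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling, stride 2; also returns the 0-based source row of each
// maximum for the backward pass
// [[Rcpp::export]]
List maxpool2(const NumericMatrix& X, int H, int W, int B) {
  const int Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  const int C = X.ncol();
  NumericMatrix out(B * HWo, C);
  IntegerMatrix idx(B * HWo, C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int r0 = b * HW + 2 * i + 2 * j * H;
          int best = r0;
          double v = X(r0, c);
          const int cand[3] = { r0 + 1, r0 + H, r0 + H + 1 };
          for (int t = 0; t < 3; ++t)
            if (X(cand[t], c) > v) { v = X(cand[t], c); best = cand[t]; }
          out(b * HWo + i + j * Ho, c) = v;
          idx(b * HWo + i + j * Ho, c) = best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_backward(const NumericMatrix& dOut,
                                const IntegerMatrix& idx, int nrowX) {
  const int C = dOut.ncol();
  NumericMatrix dX(nrowX, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < dOut.nrow(); ++r)
      dX(idx(r, c), c) += dOut(r, c);
  return dX;
}

// nearest-neighbor 2x upsampling
// [[Rcpp::export]]
NumericMatrix upsample2(const NumericMatrix& X, int H, int W, int B) {
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  const int C = X.ncol();
  NumericMatrix out(B * HWo, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          out(b * HWo + i + j * Ho, c) =
            X(b * HW + (i / 2) + (j / 2) * H, c);
  return out;
}

// [[Rcpp::export]]
NumericMatrix upsample2_backward(const NumericMatrix& dY, int H, int W, int B) {
  // H, W are the *input* (coarse) dims; dY is on the 2H x 2W grid
  const int Ho = 2 * H, HW = H * W, HWo = 4 * HW;
  const int C = dY.ncol();
  NumericMatrix dX(B * HW, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < Ho; ++i)
          dX(b * HW + (i / 2) + (j / 2) * H, c) +=
            dY(b * HWo + i + j * Ho, c);
  return dX;
}

// ---- Ising MRF / ICM ----
//
// Energy: E(x, y) = -sum_pairs x_p x_q - eta * sum x_ij y_ij, pairs being
// ((i,j),(i+1,j+1)) for the diagonal neighborhood or 4-adjacency for n4,
// no wraparound.  ICM raster sweeps; each pixel takes the sign of its
// local field (coupling neighbors + eta*y), keeping its value on ties.
// Returns the relaxed mask, sweeps used, and the energy delta of every
// accepted single-pixel update (all must be <= 0).

static inline double local_coupling(const IntegerMatrix& x, int i, int j,
                                    int H, int W, int diag) {
  double s = 0.0;
  if (diag) {
    if (i > 0 && j > 0)         s += x(i - 1, j - 1);
    if (i < H - 1 && j < W - 1) s += x(i + 1, j + 1);
  } else {
    if (i > 0)     s += x(i - 1, j);
    if (i < H - 1) s += x(i + 1, j);
    if (j > 0)     s += x(i, j - 1);
    if (j < W - 1) s += x(i, j + 1);
  }
  return s;
}

// [[Rcpp::export]]
List icm_sweeps(IntegerMatrix x, const IntegerMatrix& y, double eta,
                int diag, int max_sweeps) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<double> deltas;
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    int changed = 0;
    for (int i = 0; i < H; ++i) {         // raster scan, row-major
      for (int j = 0; j < W; ++j) {
        const double field = local_coupling(x, i, j, H, W, diag) + eta * y(i, j);
        int newv = x(i, j);
        if (field > 0) newv = 1; else if (field < 0) newv = -1;
        if (newv != x(i, j)) {
          // flipping x(i,j): dE = 2 * x_old * field
          deltas.push_back(2.0 * x(i, j) * field);
          x(i, j) = newv;
          ++changed;
        }
      }
    }
    if (changed == 0) { ++sweeps; break; }
  }
  return List::create(_["x"] = x, _["sweeps"] = sweeps,
                      _["deltas"] = NumericVector(deltas.begin(), deltas.end()));
}

// ---- batch-norm column helpers (avoid R-side sweep/aperm churn) ----

// xhat = (A - mu) * invstd;  out = xhat * gamma + beta  (per column)
// [[Rcpp::export]]
List bn_apply(const NumericMatrix& A, const NumericVector& mu,
              const NumericVector& invstd, const NumericVector& gamma,
              const NumericVector& beta) {
  const R_xlen_t n = A.nrow();
  const int C = A.ncol();
  NumericMatrix xhat(n, C), out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* a = REAL(A) + c * n;
    double* xh = REAL(xhat) + c * n;
    double* o = REAL(out) + c * n;
    const double m = mu[c], is = invstd[c], g = gamma[c], bt = beta[c];
    for (R_xlen_t r = 0; r < n; ++r) {
      xh[r] = (a[r] - m) * is;
      o[r] = xh[r] * g + bt;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// training-mode BN backward through the per-column standardization:
// dA = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)),
// dxhat = dOut * gamma; also returns dgamma, dbeta
// [[Rcpp::export]]
List bn_backward(const NumericMatrix& dOut, const NumericMatrix& xhat,
                 const NumericVector& gamma, const NumericVector& invstd,
                 bool training) {
  const R_xlen_t n = dOut.nrow();
  const int C = dOut.ncol();
  NumericMatrix dA(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = REAL(dOut) + c * n;
    const double* xh = REAL(xhat) + c * n;
    double* da = REAL(dA) + c * n;
    const double g = gamma[c], is = invstd[c];
    double s1 = 0.0, s2 = 0.0, sg = 0.0, sb = 0.0;
    for (R_xlen_t r = 0; r < n; ++r) {
      sg += dy[r] * xh[r];
      sb += dy[r];
      s1 += dy[r] * g;
      s2 += dy[r] * g * xh[r];
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double m1 = training ? s1 / n : 0.0;
    const double m2 = training ? s2 / n : 0.0;
    for (R_xlen_t r = 0; r < n; ++r)
      da[r] = is * (dy[r] * g - m1 - xh[r] * m2);
  }
  return List::create(_["dA"] = dA, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
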