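// Hot inner loops of the segmentation networks. Batches are dense
// (B*L) x C matrices, sequence-major: sequence s occupies rows
// ((s-1)*L+1):(s*L). These kernels only reorganise memory; all matrix
// products stay in R (BLAS).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// C[crow.., ] += A[arow.., ] (m x kk) * B (kk x n), with A optionally
// transposed; all matrices column-major with explicit leading dimensions.
static void dgemm_block(const char* transa, int m, int n, int kk,
                        const double* A, int lda, const double* B, int ldb,
                        double* C, int ldc, double beta) {
  const double one = 1.0;
  F77_CALL(dgemm)(transa, "N", &m, &n, &kk, &one, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// Same-length 1D convolution as k offset GEMM accumulations (no im2col).
// Each offset is one full-batch GEMM over the valid global row range; the
// few rows near sequence junctions whose windows would leak into the
// neighbouring sequence are then corrected with small rank-1 updates.
// X: (B*L) x cin, W: (k*cin) x cout (offset o occupies rows o*cin..),
// b: cout. Returns (B*L) x cout.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& X, const NumericMatrix& W,
                           const NumericVector& b, int B, int L, int k) {
  const int BL = X.nrow();
  const int cin = X.ncol();
  const int cout = W.ncol();
  const int p = (k - 1) / 2;
  const int ldw = k * cin;
  NumericMatrix Y(BL, cout);
  for (int c = 0; c < cout; ++c) {
    double* col = &Y(0, c);
    const double bc = b[c];
    for (int i = 0; i < BL; ++i) col[i] = bc;
  }
  for (int o = 0; o < k; ++o) {
    const int off = o - p;
    const int lo = std::max(0, -off);        // global valid start
    const int hi = BL - std::max(0, off);    // global valid end (excl.)
    const int m = hi - lo;
    if (m <= 0) continue;
    dgemm_block("N", m, cout, cin, &X[0] + lo + off, BL, &W[0] + o * cin,
                ldw, &Y[0] + lo, BL, 1.0);
    // remove cross-junction leakage: rows i with (i mod L) outside the
    // within-sequence valid range picked up the neighbour's residues
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      int jlo, jhi; // within-sequence invalid rows [jlo, jhi)
      if (off > 0) {
        jlo = base + L - off;
        jhi = base + L;
      } else if (off < 0) {
        jlo = base;
        jhi = base - off;
      } else {
        continue;
      }
      jlo = std::max(jlo, lo);
      jhi = std::min(jhi, hi);
      for (int i = jlo; i < jhi; ++i) {
        const double* xrow = &X[0] + i + off; // column stride BL
        for (int c = 0; c < cout; ++c) {
          const double* wcol = &W[0] + o * cin + (size_t)c * ldw;
          double acc = 0;
          for (int q = 0; q < cin; ++q) acc += xrow[(size_t)q * BL] * wcol[q];
          Y(i, c) -= acc;
        }
      }
    }
  }
  return Y;
}

// Backward of cpp_conv_fwd: returns dX, dW, db.
// [[Rcpp::export]]
List cpp_conv_bwd(const NumericMatrix& dY, const NumericMatrix& X,
                  const NumericMatrix& W, int B, int L, int k) {
  const int BL = X.nrow();
  const int cin = X.ncol();
  const int cout = W.ncol();
  const int p = (k - 1) / 2;
  const int ldw = k * cin;
  const double one = 1.0, neg = -1.0;
  const int ione = 1;
  NumericMatrix dX(BL, cin);
  NumericMatrix dW(ldw, cout);
  NumericVector db(cout);
  for (int c = 0; c < cout; ++c) {
    const double* col = &dY(0, c);
    double acc = 0;
    for (int i = 0; i < BL; ++i) acc += col[i];
    db[c] = acc;
  }
  for (int o = 0; o < k; ++o) {
    const int off = o - p;
    const int lo = std::max(0, -off);
    const int hi = BL - std::max(0, off);
    const int m = hi - lo;
    if (m <= 0) continue;
    // dW_o += X[rows+off]^T * dY[rows] over the full valid range
    dgemm_block("T", cin, cout, m, &X[0] + lo + off, BL, &dY[0] + lo, BL,
                &dW[0] + o * cin, ldw, 1.0);
    // dX[rows+off] += dY[rows] * W_o^T over the full valid range
    F77_CALL(dgemm)("N", "T", &m, &cin, &cout, &one, &dY[0] + lo, &BL,
                    &W[0] + o * cin, &ldw, &one, &dX[0] + lo + off,
                    &BL FCONE FCONE);
    // undo the cross-junction rows with rank-1 corrections
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      int jlo, jhi;
      if (off > 0) {
        jlo = base + L - off;
        jhi = base + L;
      } else if (off < 0) {
        jlo = base;
        jhi = base - off;
      } else {
        continue;
      }
      jlo = std::max(jlo, lo);
      jhi = std::min(jhi, hi);
      for (int i = jlo; i < jhi; ++i) {
        // dW_o -= X[i+off]^T dY[i]
        F77_CALL(dger)(&cin, &cout, &neg, &X[0] + i + off, &BL, &dY[0] + i,
                       &BL, &dW[0] + o * cin, &ldw);
        // dX[i+off] -= dY[i] * W_o^T
        const double* dyrow = &dY[0] + i;
        double* dxrow = &dX[0] + i + off;
        for (int q = 0; q < cin; ++q) {
          const double* wrow = &W[0] + o * cin + q;
          double acc = 0;
          for (int c = 0; c < cout; ++c)
            acc += dyrow[(size_t)c * BL] * wrow[(size_t)c * ldw];
          dxrow[(size_t)q * BL] -= acc;
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// ReLU forward in one pass: returns activated matrix and keep mask.
// [[Rcpp::export]]
List cpp_relu_fwd(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  LogicalMatrix keep(n, m);
  const double* src = &X[0];
  double* dst = &out[0];
  int* kp = &keep[0];
  const size_t total = (size_t)n * m;
  for (size_t i = 0; i < total; ++i) {
    const bool pos = src[i] > 0;
    kp[i] = pos;
    dst[i] = pos ? src[i] : 0.0;
  }
  return List::create(_["out"] = out, _["keep"] = keep);
}

// Max pooling (kernel 2, stride 2) along the sequence axis.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  const int half = n / 2;
  NumericMatrix out(half, m);
  LogicalMatrix take_a(half, m);
  for (int c = 0; c < m; ++c) {
    const double* src = &X(0, c);
    double* dst = &out(0, c);
    int* ta = &take_a[0] + (size_t)c * half;
    for (int i = 0; i < half; ++i) {
      const double a = src[2 * i], bb = src[2 * i + 1];
      const bool fa = a >= bb; // ties resolve to the earlier position
      ta[i] = fa;
      dst[i] = fa ? a : bb;
    }
  }
  return List::create(_["out"] = out, _["take_a"] = take_a);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dY,
                              const LogicalMatrix& take_a) {
  const int half = dY.nrow(), m = dY.ncol();
  NumericMatrix dX(2 * half, m);
  for (int c = 0; c < m; ++c) {
    const double* dy = &dY(0, c);
    const int* ta = &take_a[0] + (size_t)c * half;
    double* dx = &dX(0, c);
    for (int i = 0; i < half; ++i) {
      if (ta[i]) {
        dx[2 * i] = dy[i];
      } else {
        dx[2 * i + 1] = dy[i];
      }
    }
  }
  return dX;
}

// Y[i, c] = X[i, c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_add_bias(const NumericMatrix& X, const NumericVector& b) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    const double bc = b[c];
    const double* src = &X(0, c);
    double* dst = &out(0, c);
    for (int i = 0; i < n; ++i) dst[i] = src[i] + bc;
  }
  return out;
}

// Y[i, c] = X[i, c] * s[c]
// [[Rcpp::export]]
NumericMatrix cpp_scale_cols(const NumericMatrix& X, const NumericVector& s) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    const double sc = s[c];
    const double* src = &X(0, c);
    double* dst = &out(0, c);
    for (int i = 0; i < n; ++i) dst[i] = src[i] * sc;
  }
  return out;
}

// Per-column mean and mean of squares in one pass.
// [[Rcpp::export]]
List cpp_col_moments(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector mean(m), meansq(m);
  for (int c = 0; c < m; ++c) {
    const double* src = &X(0, c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      s += src[i];
      s2 += src[i] * src[i];
    }
    mean[c] = s / n;
    meansq[c] = s2 / n;
  }
  return List::create(_["mean"] = mean, _["meansq"] = meansq);
}

// Batch-norm application: xhat = (X - mu) * invstd, out = xhat*gamma + beta.
// [[Rcpp::export]]
List cpp_bn_apply(const NumericMatrix& X, const NumericVector& mu,
                  const NumericVector& invstd, const NumericVector& gamma,
                  const NumericVector& beta) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix xhat(n, m), out(n, m);
  for (int c = 0; c < m; ++c) {
    const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
    const double* src = &X(0, c);
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) {
      const double z = (src[i] - mc) * ic;
      xh[i] = z;
      o[i] = z * gc + bc;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// Training-mode batch-norm backward:
// dX = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)),
// where dxhat = dY * gamma. Also returns dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_backward(const NumericMatrix& dY, const NumericMatrix& xhat,
                     const NumericVector& invstd, const NumericVector& gamma,
                     bool training) {
  const int n = dY.nrow(), m = dY.ncol();
  NumericMatrix dX(n, m);
  NumericVector dgamma(m), dbeta(m);
  for (int c = 0; c < m; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double gc = gamma[c], ic = invstd[c];
    double* dx = &dX(0, c);
    if (training) {
      const double m1 = gc * sb / n;      // mean(dxhat)
      const double m2 = gc * sg / n;      // mean(dxhat * xhat)
      for (int i = 0; i < n; ++i)
        dx[i] = ic * (gc * dy[i] - m1 - xh[i] * m2);
    } else {
      for (int i = 0; i < n; ++i) dx[i] = ic * gc * dy[i];
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
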