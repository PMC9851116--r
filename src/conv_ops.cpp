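// Hot primitives for the 1D convolutional branches. Activations are
// n x L x C arrays (batch, time, channels); weights k x C_in x F.
// Valid convolution, stride 1. The per-tap im2col block for tap j is a
// contiguous slab of the activation memory per channel, so assembling it
// is C memcpys followed by one BLAS gemm.
//
// A whole local-branch stage (conv -> ReLU -> max-pool 2) is fused into
// one forward and one backward call; only the pooled output and a 2-bit
// routing code per pooled position (winner of the pair + whether the
// winner was ReLU-active) are kept for backprop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// alias R array memory without copying
static inline cube borrow_cube(const NumericVector& v) {
  IntegerVector d = v.attr("dim");
  return cube(const_cast<double*>(REAL(v)), d[0], d[1], d[2], false, true);
}

static inline NumericVector alloc_cube(uword n, uword L, uword C) {
  NumericVector out(n * L * C);
  out.attr("dim") = IntegerVector::create(n, L, C);
  return out;
}

static inline mat tap_weights(const cube& W, uword j) {
  uword C = W.n_cols, F = W.n_slices;
  mat Wj(C, F);
  for (uword f = 0; f < F; ++f)
    for (uword c = 0; c < C; ++c)
      Wj(c, f) = W(j, c, f);
  return Wj;
}

// Z = conv(A, W) + b as an (n*Lo) x F matrix
static mat conv_core(const cube& A, const cube& W, const vec& b) {
  uword n = A.n_rows, L = A.n_cols, C = A.n_slices;
  uword k = W.n_rows, F = W.n_slices;
  uword Lo = L - k + 1;
  mat Z(n * Lo, F);
  Z.each_row() = b.t();
  mat S(n * Lo, C);
  for (uword j = 0; j < k; ++j) {
    for (uword c = 0; c < C; ++c)
      std::memcpy(S.colptr(c), A.memptr() + n * j + n * L * c,
                  sizeof(double) * n * Lo);
    Z += S * tap_weights(W, j);
  }
  return Z;
}

// dW, db, dA from dZ given as an (n*Lo) x F matrix
static void conv_core_bwd(const cube& A, const cube& W, const mat& dZm,
                          cube& dA, cube& dW, vec& db) {
  uword n = A.n_rows, L = A.n_cols, C = A.n_slices;
  uword k = W.n_rows, F = W.n_slices;
  uword Lo = L - k + 1;
  mat S(n * Lo, C);
  for (uword j = 0; j < k; ++j) {
    for (uword c = 0; c < C; ++c)
      std::memcpy(S.colptr(c), A.memptr() + n * j + n * L * c,
                  sizeof(double) * n * Lo);
    mat dWj = S.t() * dZm;                 // C x F
    for (uword f = 0; f < F; ++f)
      for (uword c = 0; c < C; ++c)
        dW(j, c, f) = dWj(c, f);
    mat dS = dZm * tap_weights(W, j).t();  // (n*Lo) x C
    for (uword c = 0; c < C; ++c) {
      double* dst = dA.memptr() + n * j + n * L * c;
      const double* src = dS.colptr(c);
      for (uword t = 0; t < n * Lo; ++t) dst[t] += src[t];
    }
  }
  db = sum(dZm, 0).t();
}

// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(const NumericVector& A_, const NumericVector& W_,
                             const NumericVector& b_) {
  cube A = borrow_cube(A_), W = borrow_cube(W_);
  vec b(const_cast<double*>(REAL(b_)), b_.size(), false, true);
  uword Lo = A.n_cols - W.n_rows + 1;
  mat Z = conv_core(A, W, b);
  NumericVector out = alloc_cube(A.n_rows, Lo, W.n_slices);
  std::memcpy(REAL(out), Z.memptr(), sizeof(double) * Z.n_elem);
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const NumericVector& A_, const NumericVector& W_,
                    const NumericVector& dZ_) {
  cube A = borrow_cube(A_), W = borrow_cube(W_), dZc = borrow_cube(dZ_);
  uword n = A.n_rows, F = W.n_slices;
  uword Lo = A.n_cols - W.n_rows + 1;
  const mat dZm(const_cast<double*>(dZc.memptr()), n * Lo, F, false, true);
  NumericVector dA_ = alloc_cube(n, A.n_cols, A.n_slices);
  cube dA(REAL(dA_), n, A.n_cols, A.n_slices, false, true);
  cube dW(W.n_rows, W.n_cols, F, fill::zeros);
  vec db;
  conv_core_bwd(A, W, dZm, dA, dW, db);
  return List::create(_["dA"] = dA_, _["dW"] = dW, _["db"] = db);
}

// Fused conv -> ReLU -> max-pool(2). Returns the pooled activations and a
// routing code per pooled position: winner (0 = first of the pair) plus
// 2 * active (winner strictly positive after ReLU).
// [[Rcpp::export]]
List stage_fwd_cpp(const NumericVector& A_, const NumericVector& W_,
                   const NumericVector& b_) {
  cube A = borrow_cube(A_), W = borrow_cube(W_);
  vec b(const_cast<double*>(REAL(b_)), b_.size(), false, true);
  uword n = A.n_rows, F = W.n_slices;
  uword Lo = A.n_cols - W.n_rows + 1;
  uword Lp = Lo / 2;
  mat Z = conv_core(A, W, b);              // (n*Lo) x F
  NumericVector P_ = alloc_cube(n, Lp, F);
  IntegerVector code_(n * Lp * F);
  code_.attr("dim") = IntegerVector::create(n, Lp, F);
  double* p = REAL(P_);
  int* cd = INTEGER(code_);
  const double* z = Z.memptr();
  for (uword f = 0; f < F; ++f) {
    for (uword t = 0; t < Lp; ++t) {
      const double* a = z + n * (2 * t) + n * Lo * f;
      const double* bq = z + n * (2 * t + 1) + n * Lo * f;
      double* dst = p + n * t + n * Lp * f;
      int* md = cd + n * t + n * Lp * f;
      for (uword i = 0; i < n; ++i) {
        int win = a[i] >= bq[i] ? 0 : 1;
        double v = win ? bq[i] : a[i];
        int act = v > 0 ? 1 : 0;
        dst[i] = act ? v : 0.0;
        md[i] = win + 2 * act;
      }
    }
  }
  return List::create(_["P"] = P_, _["code"] = code_);
}

// [[Rcpp::export]]
List stage_bwd_cpp(const NumericVector& A_, const NumericVector& W_,
                   const NumericVector& dP_, const IntegerVector& code_) {
  cube A = borrow_cube(A_), W = borrow_cube(W_), dP = borrow_cube(dP_);
  uword n = A.n_rows, F = W.n_slices;
  uword Lo = A.n_cols - W.n_rows + 1;
  uword Lp = Lo / 2;
  mat dZm(n * Lo, F, fill::zeros);
  const double* g = dP.memptr();
  const int* cd = INTEGER(code_);
  double* z = dZm.memptr();
  for (uword f = 0; f < F; ++f) {
    for (uword t = 0; t < Lp; ++t) {
      const double* src = g + n * t + n * Lp * f;
      const int* md = cd + n * t + n * Lp * f;
      double* a = z + n * (2 * t) + n * Lo * f;
      double* bq = z + n * (2 * t + 1) + n * Lo * f;
      for (uword i = 0; i < n; ++i) {
        if (md[i] & 2) {                  // winner was ReLU-active
          if (md[i] & 1) bq[i] = src[i]; else a[i] = src[i];
        }
      }
    }
  }
  NumericVector dA_ = alloc_cube(n, A.n_cols, A.n_slices);
  cube dA(REAL(dA_), n, A.n_cols, A.n_slices, false, true);
  cube dW(W.n_rows, W.n_cols, F, fill::zeros);
  vec db;
  conv_core_bwd(A, W, dZm, dA, dW, db);
  return List::create(_["dA"] = dA_, _["dW"] = dW, _["db"] = db);
}

// Transposed (full) convolution: length L -> L + k - 1.
// [[Rcpp::export]]
NumericVector tconv1d_fwd_cpp(const NumericVector& A_, const NumericVector& W_,
                              const NumericVector& b_) {
  cube A = borrow_cube(A_), W = borrow_cube(W_);
  uword n = A.n_rows, L = A.n_cols, C = A.n_slices;
  uword k = W.n_rows, F = W.n_slices;
  uword Lo = L + k - 1;
  const mat Amat(const_cast<double*>(A.memptr()), n * L, C, false, true);
  NumericVector Out_ = alloc_cube(n, Lo, F);
  double* o = REAL(Out_);
  const double* bp = REAL(b_);
  for (uword f = 0; f < F; ++f)
    std::fill(o + n * Lo * f, o + n * Lo * (f + 1), bp[f]);
  for (uword j = 0; j < k; ++j) {
    mat contrib = Amat * tap_weights(W, j);   // (n*L) x F
    for (uword f = 0; f < F; ++f) {
      double* dst = o + n * j + n * Lo * f;
      const double* src = contrib.colptr(f);
      for (uword t = 0; t < n * L; ++t) dst[t] += src[t];
    }
  }
  return Out_;
}

// [[Rcpp::export]]
List tconv1d_bwd_cpp(const NumericVector& A_, const NumericVector& W_,
                     const NumericVector& dOut_) {
  cube A = borrow_cube(A_), W = borrow_cube(W_), dOut = borrow_cube(dOut_);
  uword n = A.n_rows, L = A.n_cols, C = A.n_slices;
  uword k = W.n_rows, F = W.n_slices;
  uword Lo = L + k - 1;
  const mat Amat(const_cast<double*>(A.memptr()), n * L, C, false, true);
  mat dAmat(n * L, C, fill::zeros);
  cube dW(k, C, F, fill::zeros);
  mat slab(n * L, F);
  for (uword j = 0; j < k; ++j) {
    for (uword f = 0; f < F; ++f)
      std::memcpy(slab.colptr(f), dOut.memptr() + n * j + n * Lo * f,
                  sizeof(double) * n * L);
    mat dWj = Amat.t() * slab;
    for (uword f = 0; f < F; ++f)
      for (uword c = 0; c < C; ++c)
        dW(j, c, f) = dWj(c, f);
    dAmat += slab * tap_weights(W, j).t();
  }
  const mat dOm(const_cast<double*>(dOut.memptr()), n * Lo, F, false, true);
  vec db = sum(dOm, 0).t();
  NumericVector dA_ = alloc_cube(n, L, C);
  std::memcpy(REAL(dA_), dAmat.memptr(), sizeof(double) * dAmat.n_elem);
  return List::create(_["dA"] = dA_, _["dW"] = dW, _["db"] = db);
}

// Max-pool of size 2 along time; ties route to the first element.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericVector& Z_) {
  cube Z = borrow_cube(Z_);
  uword n = Z.n_rows, L = Z.n_cols, C = Z.n_slices;
  uword Lp = L / 2;
  NumericVector P_ = alloc_cube(n, Lp, C);
  LogicalVector mask(n * Lp * C);
  const double* z = Z.memptr();
  double* p = REAL(P_);
  int* m = LOGICAL(mask);
  for (uword c = 0; c < C; ++c) {
    for (uword t = 0; t < Lp; ++t) {
      const double* a = z + n * (2 * t) + n * L * c;
      const double* bq = z + n * (2 * t + 1) + n * L * c;
      double* dst = p + n * t + n * Lp * c;
      int* md = m + n * t + n * Lp * c;
      for (uword i = 0; i < n; ++i) {
        bool first = a[i] >= bq[i];
        dst[i] = first ? a[i] : bq[i];
        md[i] = first;
      }
    }
  }
  mask.attr("dim") = IntegerVector::create(n, Lp, C);
  return List::create(_["P"] = P_, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const NumericVector& dP_,
                               const LogicalVector& mask) {
  cube dP = borrow_cube(dP_);
  uword n = dP.n_rows, Lp = dP.n_cols, C = dP.n_slices;
  NumericVector dZ_ = alloc_cube(n, 2 * Lp, C);
  const double* g = dP.memptr();
  const int* m = LOGICAL(mask);
  double* z = REAL(dZ_);
  for (uword c = 0; c < C; ++c) {
    for (uword t = 0; t < Lp; ++t) {
      const double* src = g + n * t + n * Lp * c;
      const int* md = m + n * t + n * Lp * c;
      double* a = z + n * (2 * t) + n * (2 * Lp) * c;
      double* bq = z + n * (2 * t + 1) + n * (2 * Lp) * c;
      for (uword i = 0; i < n; ++i) {
        if (md[i]) a[i] = src[i]; else bq[i] = src[i];
      }
    }
  }
  return dZ_;
}
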