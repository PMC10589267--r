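// Numerical hot paths: strided 1D convolution (forward/backward via
// im2col), max pooling, and batched Lorentzian accumulation for the
// spectrum synthesizer. Everything else stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_len(int L, int stride) {
  return (L + stride - 1) / stride;
}

// im2col with zero "same" padding; x is (C, L, B) flattened column-major.
// col is (C*K, L_out*B) with rows ordered c fastest, then k.
static arma::mat im2col(const double* x, int C, int L, int B, int K,
                        int stride) {
  const int Lo = out_len(L, stride);
  const int pad_total = std::max(0, (Lo - 1) * stride + K - L);
  const int pad_l = pad_total / 2;
  arma::mat col(C * K, (size_t)Lo * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)b * C * L;
    for (int l = 0; l < Lo; ++l) {
      double* dst = col.colptr((size_t)b * Lo + l);
      const int start = l * stride - pad_l; // 0-based input pos of k = 0
      for (int k = 0; k < K; ++k) {
        const int pos = start + k;
        if (pos >= 0 && pos < L) {
          const double* src = xb + (size_t)pos * C;
          std::copy(src, src + C, dst + (size_t)k * C);
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
List cpp_conv1d_forward(const NumericVector& x, const NumericMatrix& W,
                        const NumericVector& b, int C, int L, int B,
                        int K, int stride) {
  const int Lo = out_len(L, stride);
  arma::mat col = im2col(REAL(x), C, L, B, K, stride);
  arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(), false);
  arma::mat y = Wm * col;
  y.each_col() += arma::vec(const_cast<double*>(b.begin()), b.size(), false);
  NumericVector out(y.memptr(), y.memptr() + y.n_elem);
  out.attr("dim") = IntegerVector::create(W.nrow(), Lo, B);
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List cpp_conv1d_backward(const NumericVector& x, const NumericMatrix& W,
                         const NumericVector& dy, int C, int L, int B,
                         int K, int stride) {
  const int Lo = out_len(L, stride);
  const int pad_total = std::max(0, (Lo - 1) * stride + K - L);
  const int pad_l = pad_total / 2;
  const int Cout = W.nrow();
  arma::mat col = im2col(REAL(x), C, L, B, K, stride);
  arma::mat dym(const_cast<double*>(dy.begin()), Cout, (size_t)Lo * B,
                false);
  arma::mat Wm(const_cast<double*>(W.begin()), Cout, W.ncol(), false);
  arma::mat dW = dym * col.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcol = Wm.t() * dym;            // (C*K, Lo*B)
  NumericVector dx((size_t)C * L * B);      // zero-initialized
  double* dxp = REAL(dx);
  for (int b = 0; b < B; ++b) {
    double* xb = dxp + (size_t)b * C * L;
    for (int l = 0; l < Lo; ++l) {
      const double* src = dcol.colptr((size_t)b * Lo + l);
      const int start = l * stride - pad_l;
      for (int k = 0; k < K; ++k) {
        const int pos = start + k;
        if (pos >= 0 && pos < L) {
          double* dst = xb + (size_t)pos * C;
          const double* s = src + (size_t)k * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, B);
  NumericMatrix dWout(Cout, W.ncol());
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWout.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.memptr(),
                                              db.memptr() + db.n_elem));
}

// [[Rcpp::export]]
List cpp_maxpool_forward(const NumericVector& x, int C, int L, int B,
                         int p) {
  const int Lo = L / p;
  NumericVector y((size_t)C * Lo * B);
  IntegerVector arg((size_t)C * Lo * B);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  for (int b = 0; b < B; ++b) {
    for (int lo = 0; lo < Lo; ++lo) {
      const double* src = xp + ((size_t)b * L + (size_t)lo * p) * C;
      double* dst = yp + ((size_t)b * Lo + lo) * C;
      int* am = ap + ((size_t)b * Lo + lo) * C;
      for (int c = 0; c < C; ++c) { dst[c] = src[c]; am[c] = 0; }
      for (int j = 1; j < p; ++j) {
        const double* sj = src + (size_t)j * C;
        for (int c = 0; c < C; ++c) {
          if (sj[c] > dst[c]) { dst[c] = sj[c]; am[c] = j; }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Lo, B);
  arg.attr("dim") = IntegerVector::create(C, Lo, B);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(const NumericVector& dy,
                                   const IntegerVector& arg, int C, int L,
                                   int B, int p) {
  const int Lo = L / p;
  NumericVector dx((size_t)C * L * B);
  const double* dyp = REAL(dy);
  const int* ap = INTEGER(arg);
  double* dxp = REAL(dx);
  for (int b = 0; b < B; ++b) {
    for (int lo = 0; lo < Lo; ++lo) {
      const double* src = dyp + ((size_t)b * Lo + lo) * C;
      const int* am = ap + ((size_t)b * Lo + lo) * C;
      double* dst = dxp + ((size_t)b * L + (size_t)lo * p) * C;
      for (int c = 0; c < C; ++c) dst[(size_t)am[c] * C + c] = src[c];
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, B);
  return dx;
}

// Fused ReLU + inverted dropout. Returns the activation and a combined
// multiplier (0 where clipped or dropped, 1/(1-rate) where kept) so the
// backward pass is a single elementwise product. Draws from R's RNG, so
// set.seed() governs the masks.
// [[Rcpp::export]]
List cpp_relu_dropout(const NumericVector& x, double rate, bool train) {
  const R_xlen_t n = x.size();
  NumericVector y(n), mult(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* mp = REAL(mult);
  if (train && rate > 0) {
    const double inv = 1.0 / (1.0 - rate);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (xp[i] > 0 && unif_rand() >= rate) {
        yp[i] = xp[i] * inv;
        mp[i] = inv;
      }
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      if (xp[i] > 0) { yp[i] = xp[i]; mp[i] = 1.0; }
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mult"] = mult);
}

// Batched sum of unit-area Lorentzians: for each column j of `centres`
// (n_pts x B), add weights[p] * amp * L(f - centres[p, j]; gamma) to
// column j of the output (L x B).
// [[Rcpp::export]]
NumericMatrix cpp_lorentz_batch(const NumericVector& f,
                                const NumericMatrix& centres,
                                const NumericVector& weights,
                                double amp, double gamma) {
  const int L = f.size();
  const int P = centres.nrow();
  const int B = centres.ncol();
  NumericMatrix Y(L, B);
  const double hw = gamma / 2.0;
  const double hw2 = hw * hw;
  const double* fp = REAL(f);
  for (int b = 0; b < B; ++b) {
    double* yc = REAL(Y) + (size_t)b * L;
    for (int p = 0; p < P; ++p) {
      const double c = centres(p, b);
      const double s = weights[p] * amp * hw / M_PI;
      for (int i = 0; i < L; ++i) {
        const double d = fp[i] - c;
        yc[i] += s / (d * d + hw2);
      }
    }
  }
  return Y;
}
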