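// Hot-path primitives for the 1D convolutional network: im2col/col2im,
// fused batch-norm + ReLU, max pooling, and position-major flattening.
// Arrays follow the R layout (batch, length, channels), column-major; all
// functions work on the R memory directly (no container copies), matrix
// products stay in R/BLAS.

#include <Rcpp.h>
using namespace Rcpp;

static inline void get_dims3(const NumericVector& X, int& B, int& L, int& C) {
  IntegerVector d = X.attr("dim");
  B = d[0]; L = d[1]; C = d[2];
}

// (B, L, C) -> (B*Lo, k*C); column block j holds the channels at offset j.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int k) {
  int B, L, C; get_dims3(X, B, L, C);
  const int Lo = L - k + 1;
  NumericMatrix M(B * Lo, k * C);
  const double* x = X.begin();
  double* m = M.begin();
  const size_t mcol = (size_t)B * Lo;
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      double* dst = m + ((size_t)j * C + c) * mcol;
      const double* src = x + (size_t)c * B * L + (size_t)j * B;
      std::memcpy(dst, src, (size_t)B * Lo * sizeof(double));
    }
  return M;
}

// Adjoint of im2col: scatter-add (B*Lo, k*C) back into (B, L, C).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dM, int B, int L, int C, int k) {
  const int Lo = L - k + 1;
  NumericVector dX((size_t)B * L * C);
  dX.attr("dim") = IntegerVector::create(B, L, C);
  double* dx = dX.begin();
  const double* dm = dM.begin();
  const size_t mcol = (size_t)B * Lo;
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      const double* src = dm + ((size_t)j * C + c) * mcol;
      double* dst = dx + (size_t)c * B * L + (size_t)j * B;
      const size_t nn = (size_t)B * Lo;
      for (size_t i = 0; i < nn; ++i) dst[i] += src[i];
    }
  return dX;
}

// Zero-pad the length axis of (B, L, C).
// [[Rcpp::export]]
NumericVector pad_zeros_cpp(NumericVector X, int left, int right) {
  int B, L, C; get_dims3(X, B, L, C);
  const int Lp = L + left + right;
  NumericVector Xp((size_t)B * Lp * C);
  Xp.attr("dim") = IntegerVector::create(B, Lp, C);
  for (int c = 0; c < C; ++c)
    std::memcpy(Xp.begin() + (size_t)c * B * Lp + (size_t)left * B,
                X.begin() + (size_t)c * B * L, (size_t)B * L * sizeof(double));
  return Xp;
}

// a = relu(gamma * (z - mu) / sqrt(v + eps) + beta) columnwise per filter.
// Returns the activations and the normalized values (xhat); the ReLU mask
// is implicit in a > 0.
// [[Rcpp::export]]
List bn_relu_forward_cpp(NumericMatrix Z, NumericVector gamma,
                         NumericVector beta, NumericVector mu,
                         NumericVector v, double eps) {
  const int m = Z.nrow(), F = Z.ncol();
  NumericMatrix A(m, F), Xhat(m, F);
  for (int f = 0; f < F; ++f) {
    const double inv_std = 1.0 / std::sqrt(v[f] + eps);
    const double g = gamma[f], bta = beta[f], mf = mu[f];
    const double* z = &Z(0, f);
    double* xh = &Xhat(0, f);
    double* a = &A(0, f);
    for (int i = 0; i < m; ++i) {
      const double x = (z[i] - mf) * inv_std;
      xh[i] = x;
      const double y = g * x + bta;
      a[i] = y > 0 ? y : 0.0;
    }
  }
  return List::create(Named("A") = A, Named("Xhat") = Xhat);
}

// Backward through ReLU and batch norm (training-mode batch statistics).
// A is the forward activation (a > 0 recovers the ReLU mask).
// [[Rcpp::export]]
List bn_relu_backward_cpp(NumericMatrix dA, NumericMatrix A,
                          NumericMatrix Xhat, NumericVector gamma,
                          NumericVector v, double eps) {
  const int m = dA.nrow(), F = dA.ncol();
  NumericMatrix dZ(m, F);
  NumericVector dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    const double inv_std = 1.0 / std::sqrt(v[f] + eps);
    const double g = gamma[f];
    const double* da = &dA(0, f);
    const double* a = &A(0, f);
    const double* xh = &Xhat(0, f);
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    for (int i = 0; i < m; ++i) {
      const double dy = a[i] > 0 ? da[i] : 0.0;
      sg += dy * xh[i];
      sb += dy;
      const double dxh = dy * g;
      s1 += dxh;
      s2 += dxh * xh[i];
    }
    dgamma[f] = sg;
    dbeta[f] = sb;
    s1 /= m; s2 /= m;
    double* dz = &dZ(0, f);
    for (int i = 0; i < m; ++i) {
      const double dy = a[i] > 0 ? da[i] : 0.0;
      dz[i] = (dy * g - s1 - xh[i] * s2) * inv_std;
    }
  }
  return List::create(Named("dZ") = dZ, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// Max pooling over non-overlapping windows of p steps; first maximum wins.
// [[Rcpp::export]]
List pool_forward_cpp(NumericVector X, int p) {
  int B, L, C; get_dims3(X, B, L, C);
  const int Lo = L / p;
  NumericVector out((size_t)B * Lo * C);
  out.attr("dim") = IntegerVector::create(B, Lo, C);
  IntegerVector amax((size_t)B * Lo * C);
  amax.attr("dim") = IntegerVector::create(B, Lo, C);
  const double* x = X.begin();
  double* o = out.begin();
  int* am = amax.begin();
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < Lo; ++l) {
      const double* base = x + (size_t)c * B * L + (size_t)l * p * B;
      double* ob = o + (size_t)c * B * Lo + (size_t)l * B;
      int* ab = am + (size_t)c * B * Lo + (size_t)l * B;
      for (int b = 0; b < B; ++b) {
        double best = base[b];
        int arg = 0;
        for (int j = 1; j < p; ++j) {
          const double cand = base[(size_t)j * B + b];
          if (cand > best) { best = cand; arg = j; }
        }
        ob[b] = best;
        ab[b] = arg;
      }
    }
  return List::create(Named("out") = out, Named("amax") = amax);
}

// [[Rcpp::export]]
NumericVector pool_backward_cpp(NumericVector dOut, IntegerVector amax,
                                int Lin, int p) {
  int B, Lo, C; get_dims3(dOut, B, Lo, C);
  NumericVector dX((size_t)B * Lin * C);
  dX.attr("dim") = IntegerVector::create(B, Lin, C);
  const double* dov = dOut.begin();
  const int* am = amax.begin();
  double* dx = dX.begin();
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < Lo; ++l) {
      const double* db = dov + (size_t)c * B * Lo + (size_t)l * B;
      const int* ab = am + (size_t)c * B * Lo + (size_t)l * B;
      double* base = dx + (size_t)c * B * Lin + (size_t)l * p * B;
      for (int b = 0; b < B; ++b) base[(size_t)ab[b] * B + b] = db[b];
    }
  return dX;
}

// (B, L, C) -> (B, L*C) with feature index (l-1)*C + c (position-major).
// [[Rcpp::export]]
NumericMatrix flatten_cpp(NumericVector X) {
  int B, L, C; get_dims3(X, B, L, C);
  NumericMatrix M(B, L * C);
  const double* x = X.begin();
  double* m = M.begin();
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c)
      std::memcpy(m + ((size_t)l * C + c) * B,
                  x + ((size_t)c * L + l) * B, (size_t)B * sizeof(double));
  return M;
}

// [[Rcpp::export]]
NumericVector unflatten_cpp(NumericMatrix M, int L, int C) {
  const int B = M.nrow();
  NumericVector X((size_t)B * L * C);
  X.attr("dim") = IntegerVector::create(B, L, C);
  const double* m = M.begin();
  double* x = X.begin();
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c)
      std::memcpy(x + ((size_t)c * L + l) * B,
                  m + ((size_t)l * C + c) * B, (size_t)B * sizeof(double));
  return X;
}
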