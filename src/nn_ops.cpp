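#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Patch-matrix (im2col) extraction for the convolution layers.
//
// x is an activation matrix of shape (batch*S, C) where S spatial positions
// are stored row-major (row index = b + (s-1)*batch). `src` has length
// oS*K and maps (output position s, kernel offset k) -> source spatial
// index (1-based), with 0 meaning zero padding. The result P has shape
// (batch*oS, K*C) with column index (k-1) + (ci-1)*K + 1, so that
// P %*% W (with W reshaped to (K*C, Cout)) evaluates the convolution in a
// single GEMM.
// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col(NumericMatrix x, IntegerVector src,
                     int batch, int oS, int K, int C) {
  NumericMatrix out(batch * oS, K * C);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = &x(0, ci);
    for (int k = 0; k < K; ++k) {
      double* oc = &out(0, k + ci * K);
      for (int s = 0; s < oS; ++s) {
        const int sp = src[(size_t)k * oS + s];
        if (sp == 0) continue;  // matrix is zero-initialised
        const double* sc = xc + (size_t)(sp - 1) * batch;
        std::copy(sc, sc + batch, oc + (size_t)s * batch);
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch gradients back onto the activation
// grid. dP has shape (batch*oS, K*C); the result has shape (batch*S, C).
// [[Rcpp::export(name = ".col2im_add")]]
NumericMatrix col2im_add(NumericMatrix dP, IntegerVector src,
                         int batch, int S, int C) {
  const int KC = dP.ncol();
  const int K = KC / C;
  const int oS = src.size() / K;
  NumericMatrix dx(batch * S, C);
  for (int ci = 0; ci < C; ++ci) {
    double* xc = &dx(0, ci);
    for (int k = 0; k < K; ++k) {
      const double* oc = &dP(0, k + ci * K);
      for (int s = 0; s < oS; ++s) {
        const int sp = src[(size_t)k * oS + s];
        if (sp == 0) continue;
        double* dst = xc + (size_t)(sp - 1) * batch;
        const double* sc = oc + (size_t)s * batch;
        for (int b = 0; b < batch; ++b) dst[b] += sc[b];
      }
    }
  }
  return dx;
}
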