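#include <Rcpp.h>
using namespace Rcpp;

// Columnwise gather: out[k, b] = X[iv[k], b]. iv is 1-based and must lie in
// [1, nrow(X)] (checked by the caller, which precomputes it once per layer).
// This is the im2col step of the valid convolution, batched over columns.
// [[Rcpp::export]]
NumericMatrix im2col_gather(const NumericMatrix& X, const IntegerVector& iv) {
  const R_xlen_t m = iv.size();
  const int B = X.ncol(), n = X.nrow();
  NumericMatrix out((int)m, B);
  const double* xp = REAL(X);
  double* op = REAL(out);
  const int* ip = INTEGER(iv);
  for (int b = 0; b < B; ++b) {
    const double* xc = xp + (size_t)b * n;
    double* oc = op + (size_t)b * m;
    for (R_xlen_t k = 0; k < m; ++k) oc[k] = xc[ip[k] - 1];
  }
  return out;
}

// Columnwise scatter-add, the adjoint of im2col_gather:
// out[iv[k], b] += dP[k, b]. Backpropagates patch gradients to the input.
// [[Rcpp::export]]
NumericMatrix im2col_scatter(const NumericMatrix& dP, const IntegerVector& iv,
                             int in_len) {
  const R_xlen_t m = iv.size();
  const int B = dP.ncol();
  NumericMatrix out(in_len, B);
  const double* dp = REAL(dP);
  double* op = REAL(out);
  const int* ip = INTEGER(iv);
  for (int b = 0; b < B; ++b) {
    const double* dc = dp + (size_t)b * m;
    double* oc = op + (size_t)b * in_len;
    for (R_xlen_t k = 0; k < m; ++k) oc[ip[k] - 1] += dc[k];
  }
  return out;
}
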