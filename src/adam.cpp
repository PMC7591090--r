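// In-place Adam update. Parameters, moment buffers and gradients are plain
// numeric arrays owned exclusively by the training loop (freshly allocated at
// the start of every run), so mutating them in place is safe and avoids
// re-allocating megabytes per step in R.

#include <Rcpp.h>
#include <cmath>

// [[Rcpp::export]]
void cpp_adam_update(Rcpp::NumericVector param, Rcpp::NumericVector grad,
                     Rcpp::NumericVector m, Rcpp::NumericVector v,
                     double lr, double beta1, double beta2, double eps,
                     double bc1, double bc2) {
  R_xlen_t n = param.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    Rcpp::stop("adam buffers disagree in length");
  double* p = REAL(param);
  double* g = REAL(grad);
  double* mm = REAL(m);
  double* vv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * g[i];
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
}
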