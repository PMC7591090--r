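// Dense-layer kernels exploiting structure the generic BLAS path cannot:
// one-hot encoder inputs (each chess board activates exactly one unit per
// square, so the first dense layer is a gather/sum, and its weight gradient
// a scatter-add) and the per-factor softmax of the categorical-grid
// likelihood.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// First dense layer over one-hot grid input. cls is the n x F matrix of
// 1-based class indices; conceptually the input is the flattened one-hot of
// width F*C and the layer computes sigmoid(X %*% W + b). Row of W used for
// (factor f, class c) is (f-1)*C + c - 1 (0-based).
// [[Rcpp::export]]
NumericMatrix cpp_onehot_dense_forward(IntegerMatrix cls, NumericMatrix W,
                                       NumericVector b, int n_classes) {
  int n = cls.nrow(), FF = cls.ncol(), H = W.ncol();
  NumericMatrix out(n, H);
  double* o = REAL(out);
  double* w = REAL(W);
  int nrowW = W.nrow();
  // precompute active weight rows per (item, factor)
  std::vector<int> rows((size_t)n * FF);
  for (int f = 0; f < FF; ++f)
    for (int i = 0; i < n; ++i)
      rows[(size_t)f * n + i] = f * n_classes + cls(i, f) - 1;
  // walk one W column (contiguous, L1-resident) at a time
  for (int h = 0; h < H; ++h) {
    const double* wc = w + (size_t)h * nrowW;
    double* oc = o + (size_t)h * n;
    for (int f = 0; f < FF; ++f) {
      const int* rr = rows.data() + (size_t)f * n;
      for (int i = 0; i < n; ++i) oc[i] += wc[rr[i]];
    }
    for (int i = 0; i < n; ++i)
      oc[i] = 1.0 / (1.0 + std::exp(-(oc[i] + b[h])));
  }
  return out;
}

// Weight gradient of that layer: dW = X^T %*% dPre with one-hot X, i.e. a
// scatter-add of dPre rows into the active weight rows.
// [[Rcpp::export]]
NumericMatrix cpp_onehot_dense_dW(IntegerMatrix cls, NumericMatrix dPre,
                                  int n_classes) {
  int n = cls.nrow(), FF = cls.ncol(), H = dPre.ncol();
  NumericMatrix dW(FF * n_classes, H);
  double* g = REAL(dW);
  double* d = REAL(dPre);
  int nrowW = FF * n_classes;
  std::vector<int> rows((size_t)n * FF);
  for (int f = 0; f < FF; ++f)
    for (int i = 0; i < n; ++i)
      rows[(size_t)f * n + i] = f * n_classes + cls(i, f) - 1;
  // one dW column (contiguous) at a time; scatter stays inside 6.6 KB
  for (int h = 0; h < H; ++h) {
    double* gc = g + (size_t)h * nrowW;
    const double* dc = d + (size_t)h * n;
    for (int f = 0; f < FF; ++f) {
      const int* rr = rows.data() + (size_t)f * n;
      for (int i = 0; i < n; ++i) gc[rr[i]] += dc[i];
    }
  }
  return dW;
}

// Categorical-grid likelihood: per-item negative log-likelihood and gradient
// w.r.t. the logits (softmax minus one-hot), computed factor by factor.
// logits is n x (F*C), column (f-1)*C + c; cls is n x F (1-based).
// [[Rcpp::export]]
List cpp_grid_likelihood(NumericMatrix logits, IntegerMatrix cls,
                         int n_classes, bool grad) {
  int n = logits.nrow(), FF = cls.ncol();
  NumericVector recon(n);
  NumericMatrix dlogits = grad ? NumericMatrix(n, logits.ncol())
                               : NumericMatrix(0, 0);
  std::vector<double> e(n_classes);
  for (int i = 0; i < n; ++i) {
    double nll = 0.0;
    for (int f = 0; f < FF; ++f) {
      int base = f * n_classes;
      double mx = logits(i, base);
      for (int c = 1; c < n_classes; ++c)
        if (logits(i, base + c) > mx) mx = logits(i, base + c);
      double s = 0.0;
      for (int c = 0; c < n_classes; ++c) {
        e[c] = std::exp(logits(i, base + c) - mx);
        s += e[c];
      }
      int obs = cls(i, f) - 1;
      nll -= std::log(e[obs] / s);
      if (grad) {
        for (int c = 0; c < n_classes; ++c)
          dlogits(i, base + c) = e[c] / s;
        dlogits(i, base + obs) -= 1.0;
      }
    }
    recon[i] = nll;
  }
  return List::create(Named("recon") = recon, Named("dlogits") = dlogits);
}
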