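// Elementwise hot loops of the training step. Everything here mutates its
// first argument in place; callers only pass freshly allocated temporaries
// (matmul results, Adam state tensors) that hold no other references.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused Adam update with L2 weight decay: mutates par, m and v in place.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector par, NumericVector grad, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double eps, double bc1, double bc2, double wd) {
  R_xlen_t n = par.size();
  double *__restrict p = par.begin();
  const double *__restrict gr = grad.begin();
  double *__restrict mm = m.begin();
  double *__restrict vv = v.begin();
  const double c1 = lr / bc1;          // bias-corrected step size
  const double c2 = 1.0 / std::sqrt(bc2);
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    double g = gr[i] + wd * p[i];
    double mi = beta1 * mm[i] + om1 * g;
    double vi = beta2 * vv[i] + om2 * g * g;
    mm[i] = mi;
    vv[i] = vi;
    p[i] -= c1 * mi / (std::sqrt(vi) * c2 + eps);
  }
}

// A = relu(A + 1 b^T) in place (row-major broadcast of the bias vector).
// [[Rcpp::export]]
NumericMatrix cpp_bias_relu(NumericMatrix A, NumericVector b, bool relu) {
  R_xlen_t nr = A.nrow(), nc = A.ncol();
  for (R_xlen_t j = 0; j < nc; ++j) {
    double bj = b[j];
    double *col = &A(0, j);
    for (R_xlen_t i = 0; i < nr; ++i) {
      double x = col[i] + bj;
      col[i] = (relu && x < 0.0) ? 0.0 : x;
    }
  }
  return A;
}

static inline double softplus1(double a) {
  return std::log1p(std::exp(-std::fabs(a))) + (a > 0.0 ? a : 0.0);
}

// Weighted binary cross-entropy from logits, fused value + gradient:
//   loss_sum = sum_ij [ omega x sp(-a) + (1 - x) sp(a) ]
//   A <- scale * [ (1 - x) sigma(a) - omega x (1 - sigma(a)) ]   (in place)
// Returns the summed loss; the logits matrix is overwritten with the scaled
// gradient.
// [[Rcpp::export]]
double cpp_wbce_grad(NumericMatrix A, NumericMatrix X, double omega,
                     double scale) {
  R_xlen_t n = A.size();
  double *a = A.begin(), *x = X.begin();
  double loss = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double ai = a[i], xi = x[i];
    double sig = 1.0 / (1.0 + std::exp(-ai));
    loss += omega * xi * softplus1(-ai) + (1.0 - xi) * softplus1(ai);
    a[i] = scale * ((1.0 - xi) * sig - omega * xi * (1.0 - sig));
  }
  return loss;
}

// dH = (dH %*% t(W)) * (H > 0) relu mask applied in place to the first arg.
// [[Rcpp::export]]
NumericMatrix cpp_relu_mask(NumericMatrix dH, NumericMatrix H) {
  R_xlen_t n = dH.size();
  double *d = dH.begin(), *h = H.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    if (h[i] <= 0.0) d[i] = 0.0;
  return dH;
}
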