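#include <Rcpp.h>
#include "l1proj.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".project_l1_ball_cpp")]]
NumericVector project_l1_ball_cpp(NumericVector v, double radius) {
  NumericVector out = clone(v);
  project_vec_l1(out.begin(), out.size(), radius);
  return out;
}

// Bilevel l1,1 projection: allocate per-row l1 budgets by projecting the
// row-norm vector onto the l1 ball of radius eta, then project each row
// onto the ball of its budget. Rows with zero budget become exactly zero.
// [[Rcpp::export(name = ".project_l11_bilevel_cpp")]]
NumericMatrix project_l11_bilevel_cpp(NumericMatrix W, double eta) {
  NumericMatrix out = clone(W);
  project_l11_colmajor(out.begin(), out.nrow(), out.ncol(), eta);
  return out;
}

// In-place Adam update of one parameter tensor. Mutates w, m and v, which
// the training loop owns exclusively (it deep-copies the weights before
// the first step).
// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(NumericVector w, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1,
                         double beta2, double bc1, double bc2, double eps) {
  const R_xlen_t n = w.size();
  double* pw = w.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  const double* pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pw[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
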