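// Optimized projected-Adam descent loop. Mirrors the reference R
// implementation in R/train.R (run_descent_r) step for step; the test
// suite asserts numerical equivalence of the two paths on small problems.
// All randomness (batch order) is drawn in R and passed in, so results
// are reproducible from the R seed alone.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "l1proj.h"
using namespace Rcpp;

static inline void adam_update(arma::mat& w, arma::mat& m, arma::mat& v,
                               const arma::mat& g, double lr, double bc1,
                               double bc2) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

static inline void adam_update_rv(arma::rowvec& w, arma::rowvec& m,
                                  arma::rowvec& v, const arma::rowvec& g,
                                  double lr, double bc1, double bc2) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

// [[Rcpp::export(name = ".run_descent_cpp")]]
List run_descent_cpp(List weights_in, const arma::mat& X,
                     const arma::ivec& Y, double lambda, double delta,
                     double eta, double lr, int batch_size,
                     const arma::vec& class_w,
                     const arma::imat& batch_order,  // n x epochs, 1-based
                     Nullable<LogicalVector> support_mask_) {
  arma::mat W1 = as<arma::mat>(weights_in["W1"]);
  arma::mat W2 = as<arma::mat>(weights_in["W2"]);
  arma::mat W3 = as<arma::mat>(weights_in["W3"]);
  arma::mat W4 = as<arma::mat>(weights_in["W4"]);
  arma::rowvec b1v = as<arma::rowvec>(weights_in["b1"]);
  arma::rowvec b2v = as<arma::rowvec>(weights_in["b2"]);
  arma::rowvec b3v = as<arma::rowvec>(weights_in["b3"]);
  arma::rowvec b4v = as<arma::rowvec>(weights_in["b4"]);

  arma::uvec mask_dead;  // indices of frozen (deselected) gene rows
  if (support_mask_.isNotNull()) {
    LogicalVector sm(support_mask_);
    std::vector<arma::uword> dead;
    for (int i = 0; i < sm.size(); ++i) if (!sm[i]) dead.push_back(i);
    mask_dead = arma::uvec(dead);
  }

  const arma::uword n = X.n_rows;
  const int epochs = batch_order.n_cols;

  arma::mat mW1(arma::size(W1), arma::fill::zeros), vW1 = mW1;
  arma::mat mW2(arma::size(W2), arma::fill::zeros), vW2 = mW2;
  arma::mat mW3(arma::size(W3), arma::fill::zeros), vW3 = mW3;
  arma::mat mW4(arma::size(W4), arma::fill::zeros), vW4 = mW4;
  arma::rowvec mb1(arma::size(b1v), arma::fill::zeros), vb1 = mb1;
  arma::rowvec mb2(arma::size(b2v), arma::fill::zeros), vb2 = mb2;
  arma::rowvec mb3(arma::size(b3v), arma::fill::zeros), vb3 = mb3;
  arma::rowvec mb4(arma::size(b4v), arma::fill::zeros), vb4 = mb4;
  long t = 0;

  NumericVector tr_ce(epochs), tr_rec(epochs), tr_sel(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_ce = 0, ep_rec = 0;
    arma::uword ep_n = 0;
    for (arma::uword s = 0; s < n; s += batch_size) {
      arma::uword e = std::min(n, s + (arma::uword)batch_size);
      arma::uvec idx(e - s);
      for (arma::uword q = s; q < e; ++q)
        idx[q - s] = (arma::uword)batch_order(q, ep) - 1;
      const arma::uword nb = idx.n_elem;
      arma::mat Xb = X.rows(idx);

      // forward
      arma::mat H1 = Xb * W1;
      H1.each_row() += b1v;
      H1.transform([](double x) { return x > 0 ? x : 0.0; });
      arma::mat Z = H1 * W2;
      Z.each_row() += b2v;
      arma::mat H2 = Z * W3;
      H2.each_row() += b3v;
      H2.transform([](double x) { return x > 0 ? x : 0.0; });
      arma::mat Xhat = H2 * W4;
      Xhat.each_row() += b4v;

      // softmax (k = 2), weighted cross-entropy
      arma::mat P(nb, 2);
      arma::vec wrow(nb);
      double sw = 0, ce = 0;
      for (arma::uword i = 0; i < nb; ++i) {
        double zmax = std::max(Z(i, 0), Z(i, 1));
        double e0 = std::exp(Z(i, 0) - zmax), e1 = std::exp(Z(i, 1) - zmax);
        double se = e0 + e1;
        P(i, 0) = e0 / se;
        P(i, 1) = e1 / se;
        int yi = Y[idx[i]];
        wrow[i] = class_w[yi];
        sw += wrow[i];
        ce += wrow[i] * -std::log(std::max(P(i, yi), 1e-12));
      }
      ce /= sw;

      // Huber reconstruction, mean over entries
      arma::mat R = Xhat - Xb;
      double rec = 0;
      for (arma::uword q = 0; q < R.n_elem; ++q) {
        double a = std::fabs(R[q]);
        double qq = std::min(a, delta);
        rec += qq * (a - qq / 2.0);
      }
      rec /= (delta * R.n_elem);
      if (!std::isfinite(ce + lambda * rec)) {
        stop("training diverged (non-finite loss)");
      }
      ep_ce += ce * nb;
      ep_rec += rec * nb;
      ep_n += nb;

      // backward
      arma::mat dZ = P;  // CE part: (P - onehot) * w / sum(w)
      for (arma::uword i = 0; i < nb; ++i) {
        int yi = Y[idx[i]];
        dZ(i, yi) -= 1.0;
        double sc = wrow[i] / sw;
        dZ(i, 0) *= sc;
        dZ(i, 1) *= sc;
      }
      arma::mat dXhat = R;
      const double rscale = lambda / (double)R.n_elem;
      dXhat.transform([delta, rscale](double x) {
        double c = x / delta;
        if (c > 1) c = 1; else if (c < -1) c = -1;
        return c * rscale;
      });

      arma::mat dW4 = H2.t() * dXhat;
      arma::rowvec db4 = arma::sum(dXhat, 0);
      arma::mat dH2 = dXhat * W4.t();
      dH2.elem(arma::find(H2 <= 0)).zeros();
      arma::mat dW3 = Z.t() * dH2;
      arma::rowvec db3 = arma::sum(dH2, 0);
      dZ += dH2 * W3.t();
      arma::mat dW2 = H1.t() * dZ;
      arma::rowvec db2 = arma::sum(dZ, 0);
      arma::mat dH1 = dZ * W2.t();
      dH1.elem(arma::find(H1 <= 0)).zeros();
      arma::mat dW1 = Xb.t() * dH1;
      arma::rowvec db1 = arma::sum(dH1, 0);

      if (mask_dead.n_elem) dW1.rows(mask_dead).zeros();

      ++t;
      double bc1 = 1.0 - std::pow(0.9, (double)t);
      double bc2 = 1.0 - std::pow(0.999, (double)t);
      adam_update(W1, mW1, vW1, dW1, lr, bc1, bc2);
      adam_update(W2, mW2, vW2, dW2, lr, bc1, bc2);
      adam_update(W3, mW3, vW3, dW3, lr, bc1, bc2);
      adam_update(W4, mW4, vW4, dW4, lr, bc1, bc2);
      adam_update_rv(b1v, mb1, vb1, db1, lr, bc1, bc2);
      adam_update_rv(b2v, mb2, vb2, db2, lr, bc1, bc2);
      adam_update_rv(b3v, mb3, vb3, db3, lr, bc1, bc2);
      adam_update_rv(b4v, mb4, vb4, db4, lr, bc1, bc2);

      project_l11_colmajor(W1.memptr(), W1.n_rows, W1.n_cols, eta);
      if (mask_dead.n_elem) W1.rows(mask_dead).zeros();
    }
    tr_ce[ep] = ep_ce / ep_n;
    tr_rec[ep] = ep_rec / ep_n;
    arma::uword nz = 0;
    for (arma::uword i = 0; i < W1.n_rows; ++i) {
      if (arma::accu(arma::abs(W1.row(i))) > 1e-12) ++nz;
    }
    tr_sel[ep] = (double)nz / (double)W1.n_rows;
  }

  List w = List::create(
      Named("W1") = W1, Named("b1") = NumericVector(b1v.begin(), b1v.end()),
      Named("W2") = W2, Named("b2") = NumericVector(b2v.begin(), b2v.end()),
      Named("W3") = W3, Named("b3") = NumericVector(b3v.begin(), b3v.end()),
      Named("W4") = W4, Named("b4") = NumericVector(b4v.begin(), b4v.end()));
  w.attr("class") = "ssae_weights";
  return List::create(Named("weights") = w, Named("ce") = tr_ce,
                      Named("reconstruction") = tr_rec,
                      Named("selected_fraction") = tr_sel);
}
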