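// Graph-autoencoder training loop: two GraphSAGE layers (undirected mean
// aggregation), bilinear sigmoid decoder, BCE loss over a labelled pair
// set, Adam updates, per-epoch edge and feature dropout. Dropout draws
// come from R's RNG so a set.seed() in R makes training reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

static mat relu_grad(const mat& s) { return conv_to<mat>::from(s > 0); }

// mean-aggregation operator over kept undirected edges; rows with no
// kept neighbour stay zero (empty-neighbourhood convention)
static mat build_aggregator(int m, const umat& uedges, const uvec& keep) {
  mat M(m, m, fill::zeros);
  vec deg(m, fill::zeros);
  for (uword e = 0; e < uedges.n_rows; ++e) {
    if (!keep(e)) continue;
    uword a = uedges(e, 0), b = uedges(e, 1);
    M(a, b) += 1.0; M(b, a) += 1.0;
    deg(a) += 1.0; deg(b) += 1.0;
  }
  for (int i = 0; i < m; ++i) if (deg(i) > 0) M.row(i) /= deg(i);
  return M;
}

struct Adam {
  mat mth, vth;
  Adam(const mat& w) : mth(size(w), fill::zeros), vth(size(w), fill::zeros) {}
  void step(mat& w, const mat& g, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mth = b1 * mth + (1 - b1) * g;
    vth = b2 * vth + (1 - b2) * square(g);
    mat mhat = mth / (1 - std::pow(b1, t));
    mat vhat = vth / (1 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
};

// [[Rcpp::export]]
Rcpp::List gae_train_cpp(const arma::mat& X, const arma::umat& uedges,
                         const arma::umat& pairs, const arma::vec& labels,
                         const Rcpp::List& w0, double lr, int epochs,
                         double pe, double pd) {
  const int m = X.n_rows;
  mat W11 = w0["W1_1"], W21 = w0["W2_1"];
  mat W12 = w0["W1_2"], W22 = w0["W2_2"], W3 = w0["W3"];
  const int h = W11.n_rows;
  Adam a11(W11), a21(W21), a12(W12), a22(W22), a3(W3);
  const int npairs = pairs.n_rows;
  if (npairs == 0) Rcpp::stop("empty training pair set");
  double loss = NA_REAL;
  uvec keep(uedges.n_rows);

  for (int ep = 0; ep < epochs; ++ep) {
    for (uword e = 0; e < uedges.n_rows; ++e)
      keep(e) = (pe <= 0.0 || unif_rand() >= pe) ? 1u : 0u;
    mat M = build_aggregator(m, uedges, keep);
    mat D(m, h, fill::ones);
    if (pd > 0) {
      const double s = 1.0 / (1.0 - pd);
      for (uword k = 0; k < D.n_elem; ++k)
        D(k) = (unif_rand() >= pd) ? s : 0.0;
    }
    // forward
    mat MX = M * X;
    mat S1 = X * W11.t() + MX * W21.t();
    mat H1 = relu(S1) % D;
    mat MH = M * H1;
    mat S2 = H1 * W12.t() + MH * W22.t();
    mat Z = relu(S2);
    mat L = Z * W3 * Z.t();
    // BCE over labelled pairs; G = dLoss/dLogits
    mat G(m, m, fill::zeros);
    loss = 0.0;
    for (int p = 0; p < npairs; ++p) {
      uword i = pairs(p, 0), j = pairs(p, 1);
      double sc = 1.0 / (1.0 + std::exp(-L(i, j)));
      double scl = std::min(std::max(sc, 1e-7), 1.0 - 1e-7);
      loss -= labels(p) * std::log(scl) + (1.0 - labels(p)) * std::log(1.0 - scl);
      G(i, j) += (sc - labels(p)) / npairs;
    }
    loss /= npairs;
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    // backward
    mat dW3 = Z.t() * G * Z;
    mat dZ = G * Z * W3.t() + G.t() * Z * W3;
    mat dS2 = dZ % relu_grad(S2);
    mat dW12 = dS2.t() * H1;
    mat dW22 = dS2.t() * MH;
    mat dH1 = (dS2 * W12 + M.t() * dS2 * W22) % D % relu_grad(S1);
    mat dW11 = dH1.t() * X;
    mat dW21 = dH1.t() * MX;
    int t = ep + 1;
    a11.step(W11, dW11, lr, t); a21.step(W21, dW21, lr, t);
    a12.step(W12, dW12, lr, t); a22.step(W22, dW22, lr, t);
    a3.step(W3, dW3, lr, t);
  }
  return Rcpp::List::create(
    Rcpp::Named("W1_1") = W11, Rcpp::Named("W2_1") = W21,
    Rcpp::Named("W1_2") = W12, Rcpp::Named("W2_2") = W22,
    Rcpp::Named("W3") = W3, Rcpp::Named("final_loss") = loss);
}
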