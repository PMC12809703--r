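// Feed-forward network trainer: one or two tanh hidden layers, linear
// output, full-batch Adam on the training-subset MSE, early stopping driven
// by the validation subset (best-validation weights are restored).
// Deterministic given the initial weights passed in from R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Net {
  mat W1, W2, W3;
  rowvec b1, b2, b3;
  bool two_layers;
};

static mat forward(const Net &net, const mat &X, mat &H1, mat &H2) {
  H1 = tanh(X * net.W1 + repmat(net.b1, X.n_rows, 1));
  if (net.two_layers) {
    H2 = tanh(H1 * net.W2 + repmat(net.b2, X.n_rows, 1));
    return H2 * net.W3 + repmat(net.b3, X.n_rows, 1);
  }
  return H1 * net.W3 + repmat(net.b3, X.n_rows, 1);
}

struct Adam {
  mat m, v;
  int t = 0;
  explicit Adam(const mat &shape) : m(size(shape), fill::zeros),
                                    v(size(shape), fill::zeros) {}
  void step(mat &w, const mat &g, double lr) {
    ++t;
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * square(g);
    mat mh = m / (1.0 - std::pow(0.9, t));
    mat vh = v / (1.0 - std::pow(0.999, t));
    w -= lr * mh / (sqrt(vh) + 1e-8);
  }
};

// [[Rcpp::export]]
Rcpp::List ann_train_cpp(const arma::mat &X, const arma::mat &T,
                         const arma::uvec &tr_idx, const arma::uvec &va_idx,
                         int n1, int n2,
                         const arma::mat &W1, const arma::rowvec &b1,
                         const arma::mat &W2, const arma::rowvec &b2,
                         const arma::mat &W3, const arma::rowvec &b3,
                         int max_epochs, int patience, double lr) {
  Net net{W1, W2, W3, b1, b2, b3, n2 > 0};
  mat Xtr = X.rows(tr_idx), Ttr = T.rows(tr_idx);
  mat Xva = X.rows(va_idx), Tva = T.rows(va_idx);
  const double ncell = static_cast<double>(Ttr.n_elem);

  Adam aW1(net.W1), aW2(net.W2), aW3(net.W3);
  Adam ab1(net.b1), ab2(net.b2), ab3(net.b3);

  Net best = net;
  double best_va = datum::inf;
  int best_epoch = 0, stall = 0, epoch = 0;
  std::vector<double> va_hist;
  va_hist.reserve(max_epochs);

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    mat H1, H2;
    mat Y = forward(net, Xtr, H1, H2);
    mat dY = 2.0 * (Y - Ttr) / ncell;   // d(MSE)/dY

    mat gW3, dH;
    rowvec gb3 = sum(dY, 0);
    if (net.two_layers) {
      gW3 = H2.t() * dY;
      mat dH2 = (dY * net.W3.t()) % (1.0 - square(H2));
      rowvec gb2 = sum(dH2, 0);
      mat gW2 = H1.t() * dH2;
      mat dH1 = (dH2 * net.W2.t()) % (1.0 - square(H1));
      mat gW1 = Xtr.t() * dH1;
      rowvec gb1 = sum(dH1, 0);
      aW3.step(net.W3, gW3, lr);
      mat b3m = net.b3; ab3.step(b3m, gb3, lr); net.b3 = b3m;
      aW2.step(net.W2, gW2, lr);
      mat b2m = net.b2; ab2.step(b2m, gb2, lr); net.b2 = b2m;
      aW1.step(net.W1, gW1, lr);
      mat b1m = net.b1; ab1.step(b1m, gb1, lr); net.b1 = b1m;
    } else {
      gW3 = H1.t() * dY;
      mat dH1 = (dY * net.W3.t()) % (1.0 - square(H1));
      mat gW1 = Xtr.t() * dH1;
      rowvec gb1 = sum(dH1, 0);
      aW3.step(net.W3, gW3, lr);
      mat b3m = net.b3; ab3.step(b3m, gb3, lr); net.b3 = b3m;
      aW1.step(net.W1, gW1, lr);
      mat b1m = net.b1; ab1.step(b1m, gb1, lr); net.b1 = b1m;
    }

    mat H1v, H2v;
    mat Yva = forward(net, Xva, H1v, H2v);
    double va_mse = accu(square(Yva - Tva)) / Tva.n_elem;
    va_hist.push_back(va_mse);
    if (va_mse < best_va) {
      best_va = va_mse;
      best = net;
      best_epoch = epoch;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  mat H1f, H2f;
  mat Ytr = forward(best, Xtr, H1f, H2f);
  double tr_mse = accu(square(Ytr - Ttr)) / Ttr.n_elem;

  return Rcpp::List::create(
    Rcpp::Named("W1") = best.W1, Rcpp::Named("b1") = best.b1,
    Rcpp::Named("W2") = best.W2, Rcpp::Named("b2") = best.b2,
    Rcpp::Named("W3") = best.W3, Rcpp::Named("b3") = best.b3,
    Rcpp::Named("va_mse") = best_va,
    Rcpp::Named("tr_mse") = tr_mse,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = std::min(epoch, max_epochs),
    Rcpp::Named("va_history") = va_hist);
}
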