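// Minibatch fully-connected network trainer (Adamax) used by both the
// deep autoencoders and the DNN classifiers.  Samples are stored as
// columns internally so weight matrices have shape (out x in), matching
// the usual vectorized layer notation x_l = a(W_l x_{l-1} + b_l).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum Act { LINEAR = 0, RELU = 1, TANH = 2, SIGMOID = 3 };

static arma::mat apply_act(const arma::mat& z, int act) {
  switch (act) {
  case RELU:    return arma::clamp(z, 0.0, arma::datum::inf);
  case TANH:    return arma::tanh(z);
  case SIGMOID: return 1.0 / (1.0 + arma::exp(-z));
  default:      return z;
  }
}

// derivative expressed through the activation value a = act(z)
static arma::mat act_deriv(const arma::mat& a, int act) {
  switch (act) {
  case RELU:    return arma::conv_to<arma::mat>::from(a > 0.0);
  case TANH:    return 1.0 - arma::square(a);
  case SIGMOID: return a % (1.0 - a);
  default:      return arma::ones<arma::mat>(a.n_rows, a.n_cols);
  }
}

static std::vector<arma::mat> as_mats(List L) {
  std::vector<arma::mat> out;
  for (int i = 0; i < L.size(); ++i) out.push_back(as<arma::mat>(L[i]));
  return out;
}

static std::vector<arma::vec> as_vecs(List L) {
  std::vector<arma::vec> out;
  for (int i = 0; i < L.size(); ++i) out.push_back(as<arma::vec>(L[i]));
  return out;
}

// forward pass; A holds input as (d x m)
static arma::mat forward_all(const arma::mat& A0,
                             const std::vector<arma::mat>& W,
                             const std::vector<arma::vec>& b,
                             const IntegerVector& act) {
  arma::mat A = A0;
  for (size_t l = 0; l < W.size(); ++l) {
    arma::mat Z = W[l] * A;
    Z.each_col() += b[l];
    A = apply_act(Z, act[l]);
  }
  return A;
}

static double full_loss(const arma::mat& Xt, const arma::mat& Yt,
                        const std::vector<arma::mat>& W,
                        const std::vector<arma::vec>& b,
                        const IntegerVector& act, int loss) {
  arma::mat A = forward_all(Xt, W, b, act);
  if (loss == 1) { // binary cross-entropy
    const double eps = 1e-12;
    arma::mat P = arma::clamp(A, eps, 1.0 - eps);
    return arma::accu(-(Yt % arma::log(P) + (1.0 - Yt) % arma::log(1.0 - P))) /
           (double)(Yt.n_cols * Yt.n_rows);
  }
  return arma::accu(arma::square(A - Yt)) / (double)(Yt.n_cols * Yt.n_rows);
}

// Fisher-Yates shuffle driven by R's RNG so results follow set.seed()
static void shuffle_idx(std::vector<arma::uword>& idx) {
  for (size_t i = idx.size(); i > 1; --i) {
    size_t j = (size_t)(unif_rand() * i);
    if (j >= i) j = i - 1;
    std::swap(idx[i - 1], idx[j]);
  }
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Y, List W0, List b0,
                   IntegerVector act, int loss, double lr, int epochs,
                   int batch_size, bool shuffle) {
  RNGScope scope;
  std::vector<arma::mat> W = as_mats(W0);
  std::vector<arma::vec> b = as_vecs(b0);
  const size_t L = W.size();
  const arma::uword n = X.n_rows;
  const arma::mat Xt = X.t();          // d x n
  const arma::mat Yt = Y.t();          // k x n

  // Adamax state
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  std::vector<arma::mat> mW(L), uW(L);
  std::vector<arma::vec> mb(L), ub(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(W[l])); uW[l].zeros(arma::size(W[l]));
    mb[l].zeros(arma::size(b[l])); ub[l].zeros(arma::size(b[l]));
  }

  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  NumericVector epoch_loss(epochs);
  long t = 0;

  std::vector<arma::mat> A(L + 1), delta(L);
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) shuffle_idx(idx);
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword stop = std::min<arma::uword>(start + batch_size, n);
      arma::uvec bidx(stop - start);
      for (arma::uword i = start; i < stop; ++i) bidx[i - start] = idx[i];
      const double m = (double)bidx.n_elem;

      A[0] = Xt.cols(bidx);
      for (size_t l = 0; l < L; ++l) {
        arma::mat Z = W[l] * A[l];
        Z.each_col() += b[l];
        A[l + 1] = apply_act(Z, act[l]);
      }
      const arma::mat Yb = Yt.cols(bidx);

      // output delta = dLoss/dZ_L
      if (loss == 1) {
        // bce with sigmoid output collapses to (a - y)/m
        delta[L - 1] = (A[L] - Yb) / (m * (double)Yb.n_rows);
      } else {
        delta[L - 1] = (2.0 / (m * (double)Yb.n_rows)) * (A[L] - Yb) %
                       act_deriv(A[L], act[L - 1]);
      }
      for (size_t l = L - 1; l > 0; --l)
        delta[l - 1] = (W[l].t() * delta[l]) % act_deriv(A[l], act[l - 1]);

      ++t;
      const double step = lr / (1.0 - std::pow(beta1, (double)t));
      for (size_t l = 0; l < L; ++l) {
        arma::mat gW = delta[l] * A[l].t();
        arma::vec gb = arma::sum(delta[l], 1);
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        uW[l] = arma::max(beta2 * uW[l], arma::abs(gW));
        W[l] -= step * mW[l] / (uW[l] + eps);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        ub[l] = arma::max(beta2 * ub[l], arma::abs(gb));
        b[l] -= step * mb[l] / (ub[l] + eps);
      }
    }
    epoch_loss[ep] = full_loss(Xt, Yt, W, b, act, loss);
    if (!std::isfinite(epoch_loss[ep]))
      stop("non-finite training loss at epoch %d; lower the learning rate",
           ep + 1);
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = wrap(b[l]); }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
arma::mat mlp_forward_cpp(const arma::mat& X, List W0, List b0,
                          IntegerVector act) {
  std::vector<arma::mat> W = as_mats(W0);
  std::vector<arma::vec> b = as_vecs(b0);
  return forward_all(X.t(), W, b, act).t();
}
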