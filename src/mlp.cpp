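// Feed-forward multi-class classifier: ReLU hidden layers, softmax
// output, categorical cross-entropy, Adam optimizer with minibatch
// SGD. All randomness (initialization, epoch shuffling) flows through
// one std::mt19937_64 seeded per call, so runs are reproducible in
// single-threaded mode.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// He-normal initialization, fan-in scaled; biases zero.
// widths = c(input, hidden..., classes)
// [[Rcpp::export]]
List cpp_mlp_init(IntegerVector widths, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  int L = widths.size() - 1;
  List W(L), b(L);
  for (int l = 0; l < L; ++l) {
    int nin = widths[l], nout = widths[l + 1];
    arma::mat w(nin, nout);
    double sc = std::sqrt(2.0 / nin);
    for (arma::uword j = 0; j < w.n_cols; ++j)
      for (arma::uword i = 0; i < w.n_rows; ++i)
        w(i, j) = sc * norm(rng);
    W[l] = w;
    b[l] = arma::rowvec(nout, arma::fill::zeros);
  }
  return List::create(_["W"] = W, _["b"] = b);
}

static arma::mat softmax_rows(arma::mat z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  arma::vec s = arma::sum(z, 1);
  z.each_col() /= s;
  return z;
}

// Forward pass returning per-layer activations (A[0] = input).
static std::vector<arma::mat> forward_all(const std::vector<arma::mat>& W,
                                          const std::vector<arma::rowvec>& b,
                                          const arma::mat& X) {
  size_t L = W.size();
  std::vector<arma::mat> A(L + 1);
  A[0] = X;
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = A[l] * W[l];
    Z.each_row() += b[l];
    if (l + 1 < L) {
      A[l + 1] = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
    } else {
      A[l + 1] = softmax_rows(Z);
    }
  }
  return A;
}

static void unpack(const List& params, std::vector<arma::mat>& W,
                   std::vector<arma::rowvec>& b) {
  List Wl = params["W"], bl = params["b"];
  size_t L = Wl.size();
  W.resize(L); b.resize(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(Wl[l]);
    b[l] = as<arma::rowvec>(bl[l]);
  }
}

// [[Rcpp::export]]
arma::mat cpp_mlp_predict(List params, arma::mat X) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  unpack(params, W, b);
  return forward_all(W, b, X).back();
}

// Fused single-pass Adam step over one parameter block.
static inline void adam_update(double* w, double* m, double* v,
                               const double* g, arma::uword n, double lr,
                               double beta1, double beta2, double bc1,
                               double bc2, double eps) {
  const double sbc2 = std::sqrt(bc2);
  for (arma::uword i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i]) / sbc2 + eps);
  }
}

// Train with Adam. y is a 0-based integer class vector; history
// reports the running mean of per-batch loss/accuracy over each epoch
// (the convention of the usual deep-learning toolkits).
// [[Rcpp::export]]
List cpp_mlp_train(List params, arma::mat X, IntegerVector y, int n_classes,
                   double lr, int epochs, int batch_size, int seed,
                   double beta1 = 0.9, double beta2 = 0.999,
                   double eps = 1e-8) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  unpack(params, W, b);
  size_t L = W.size();
  arma::uword n = X.n_rows;

  arma::mat Y(n, n_classes, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) Y(i, y[i]) = 1.0;

  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  NumericVector hist_loss(epochs), hist_acc(epochs);
  long step = 0;

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates shuffle driven by the call's RNG
    for (arma::uword i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<arma::uword> d(0, i);
      std::swap(idx[i], idx[d(rng)]);
    }
    double ep_loss = 0.0, ep_correct = 0.0;
    arma::uword seen = 0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword end = std::min(n, start + (arma::uword)batch_size);
      arma::uvec rows(end - start);
      for (arma::uword i = start; i < end; ++i) rows[i - start] = idx[i];
      arma::mat Xb = X.rows(rows), Yb = Y.rows(rows);
      double m = (double)Xb.n_rows;

      std::vector<arma::mat> A = forward_all(W, b, Xb);
      arma::mat P = A.back();

      ep_loss += -arma::accu(Yb % arma::log(arma::clamp(P, 1e-12, 1.0)));
      arma::uvec pred = arma::index_max(P, 1);
      arma::uvec truth = arma::index_max(Yb, 1);
      ep_correct += (double)arma::accu(pred == truth);
      seen += Xb.n_rows;

      // backprop
      arma::mat delta = (P - Yb) / m;      // dL/dZ_out, mean loss
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = (int)L - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          arma::mat dA = delta * W[l].t();
          delta = dA % arma::conv_to<arma::mat>::from(A[l] > 0.0);
        }
        adam_update(W[l].memptr(), mW[l].memptr(), vW[l].memptr(),
                    gW.memptr(), W[l].n_elem, lr, beta1, beta2, bc1, bc2, eps);
        adam_update(b[l].memptr(), mb[l].memptr(), vb[l].memptr(),
                    gb.memptr(), b[l].n_elem, lr, beta1, beta2, bc1, bc2, eps);
      }
    }
    hist_loss[e] = ep_loss / (double)seen;
    hist_acc[e] = ep_correct / (double)seen;
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss"] = hist_loss, _["accuracy"] = hist_acc);
}
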